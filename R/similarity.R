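#' Chemical similarity configuration
#'
#' The similarity stage scores drug pairs with a two-component combo score
#' in [0, 2]: a structural-fingerprint Tanimoto plus a
#' chemical-feature-fingerprint Tanimoto, mirroring the shape + color
#' decomposition of 3D combo scoring while staying fully deterministic and
#' dependency-light. Two scorers are built in:
#' \describe{
#'   \item{\code{openbabel}}{Open Babel path fingerprints (FP2, 1024 bits)
#'     as the structural component and functional-group fingerprints (FP4,
#'     512 bits) as the feature component, via ChemmineOB. Equivalent SMILES
#'     parse to the same molecular graph, so descriptors are canonical.}
#'   \item{\code{hex}}{precomputed fingerprints serialized as a hex string
#'     standing in the SMILES slot (structural half first); used by the
#'     synthetic library generator so the whole pipeline runs without a
#'     chemistry backend.}
#' }
#'
#' @param combo_threshold retain pairs scoring at least this, in [0, 2].
#' @param fp_length bits per fingerprint component for the \code{hex}
#'   scorer (the Open Babel scorer has fixed component lengths 1024/512).
#' @param scorer \code{"hex"} or \code{"openbabel"}.
#' @return a list of class \code{similarity_config}.
#' @export
similarity_config <- function(combo_threshold = 1.5, fp_length = 256L,
                              scorer = c("hex", "openbabel")) {
  cfg <- list(
    combo_threshold = check_scalar(combo_threshold, "combo_threshold", 0, 2),
    fp_length = check_count(fp_length, "fp_length", min = 8L),
    scorer = match.arg(scorer)
  )
  class(cfg) <- "similarity_config"
  cfg
}

#' Molecule descriptor
#'
#' A pair of fixed-length binary fingerprints for one drug: structural and
#' chemical-feature components of the combo score.
#'
#' @param drug_id drug identifier.
#' @param fp_structural,fp_feature 0/1 integer vectors.
#' @param scorer scorer id the descriptor was produced under.
#' @return an object of class \code{mol_descriptor}.
#' @export
mol_descriptor <- function(drug_id, fp_structural, fp_feature, scorer) {
  fp_structural <- as.integer(fp_structural)
  fp_feature <- as.integer(fp_feature)
  if (!all(fp_structural %in% 0:1) || !all(fp_feature %in% 0:1)) {
    stop("fingerprints must be 0/1 vectors", call. = FALSE)
  }
  structure(list(drug_id = as.character(drug_id), fp_structural = fp_structural,
                 fp_feature = fp_feature, scorer = as.character(scorer)),
            class = "mol_descriptor")
}

# hex <-> bit vector; nbits must be a multiple of 4
fp_to_hex <- function(bits) {
  stopifnot(length(bits) %% 4L == 0L)
  nib <- matrix(as.integer(bits), nrow = 4L)
  vals <- colSums(nib * c(8L, 4L, 2L, 1L))
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[vals + 1L], collapse = "")
}

fp_from_hex <- function(hex) {
  chars <- strsplit(tolower(hex), "")[[1L]]
  vals <- match(chars, c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
                         "a", "b", "c", "d", "e", "f")) - 1L
  if (anyNA(vals)) stop("invalid hex fingerprint string", call. = FALSE)
  as.integer(vapply(vals, function(v) as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L),
                    integer(4L)))
}

#' Compute a molecule descriptor
#'
#' Turns one molecule record into its two-component fingerprint descriptor
#' under the configured scorer. For the \code{openbabel} scorer the record
#' is a SMILES string; equivalent SMILES of the same molecule yield
#' identical descriptors. For the \code{hex} scorer the record is a hex
#' string carrying \code{2 * fp_length} precomputed bits (structural half
#' first).
#'
#' @param smiles the molecule record (SMILES or hex string).
#' @param config a \code{\link{similarity_config}}.
#' @param drug_id identifier used in the descriptor and error messages.
#' @return a \code{\link{mol_descriptor}}.
#' @export
featurize <- function(smiles, config = similarity_config(), drug_id = "molecule") {
  stopifnot(inherits(config, "similarity_config"))
  if (config$scorer == "hex") {
    nhex <- 2L * config$fp_length / 4L
    if (!is.character(smiles) || nchar(smiles) != nhex) {
      stop(sprintf("drug %s: hex fingerprint must have %d hex characters",
                   drug_id, nhex), call. = FALSE)
    }
    bits <- fp_from_hex(smiles)
    fs <- bits[seq_len(config$fp_length)]
    ff <- bits[config$fp_length + seq_len(config$fp_length)]
    if (sum(fs) == 0L || sum(ff) == 0L) {
      stop(sprintf("drug %s: empty fingerprint component", drug_id), call. = FALSE)
    }
    return(mol_descriptor(drug_id, fs, ff, "hex"))
  }
  featurize_openbabel(smiles, drug_id)[[1L]]
}

# batch Open Babel featurization; returns a named list of descriptors
featurize_openbabel <- function(smiles, drug_ids) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("the 'openbabel' scorer needs the ChemmineR and ChemmineOB packages",
         call. = FALSE)
  }
  smiles <- as.character(smiles)
  names(smiles) <- drug_ids
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop(sprintf("unparsable SMILES for drug(s) %s: %s",
                                     paste(drug_ids, collapse = ", "),
                                     conditionMessage(e)), call. = FALSE))
  valid <- ChemmineR::validSDF(sdf)
  if (!all(valid)) {
    stop(sprintf("unparsable SMILES for drug(s): %s",
                 paste(drug_ids[!valid], collapse = ", ")), call. = FALSE)
  }
  fp2 <- ChemmineR::fingerprintOB(sdf, "FP2")@fpma
  fp4 <- ChemmineR::fingerprintOB(sdf, "FP4")@fpma
  empty <- rowSums(fp2) == 0 | rowSums(fp4) == 0
  if (any(empty)) {
    stop(sprintf("empty fingerprint component for drug(s): %s (molecule too featureless for FP2/FP4)",
                 paste(drug_ids[empty], collapse = ", ")), call. = FALSE)
  }
  out <- lapply(seq_along(drug_ids), function(i) {
    mol_descriptor(drug_ids[i], fp2[i, ], fp4[i, ], "openbabel")
  })
  names(out) <- drug_ids
  out
}

#' Tanimoto coefficient of two fingerprints
#'
#' \eqn{|a \wedge b| / |a \vee b|}; defined as 1 when both vectors are
#' all-zero (two empty molecules are identical), though
#' \code{\link{featurize}} rejects empty fingerprints upstream.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0L) return(1)
  sum(a & b) / un
}

#' Two-component combo similarity score
#'
#' Structural Tanimoto plus feature Tanimoto, in [0, 2]; symmetric, and 2
#' for identical descriptors.
#'
#' @param d1,d2 \code{\link{mol_descriptor}} objects from the same scorer
#'   configuration.
#' @return score in [0, 2].
#' @export
combo_score <- function(d1, d2) {
  stopifnot(inherits(d1, "mol_descriptor"), inherits(d2, "mol_descriptor"))
  if (d1$scorer != d2$scorer ||
      length(d1$fp_structural) != length(d2$fp_structural) ||
      length(d1$fp_feature) != length(d2$fp_feature)) {
    stop("descriptors come from different scorer configurations", call. = FALSE)
  }
  tanimoto(d1$fp_structural, d2$fp_structural) +
    tanimoto(d1$fp_feature, d2$fp_feature)
}

# max combo score of each query descriptor against a reference list
max_combo <- function(queries, reference) {
  vapply(queries, function(d) {
    max(vapply(reference, function(r) combo_score(d, r), 0))
  }, 0)
}

#' Expand a reference set around known drugs
#'
#' Screens a drug library for members whose best combo score against any
#' known drug reaches \code{threshold}; the known drugs themselves are
#' always part of the result. This reproduces the step of building a
#' similarity reference panel around the known ligands before the final
#' filter.
#'
#' @param known named list of \code{\link{mol_descriptor}} for known drugs
#'   (non-empty).
#' @param library named list of descriptors for the library to screen.
#' @param threshold combo-score cut for inclusion.
#' @return sorted character vector of reference drug ids.
#' @export
expand_reference <- function(known, library, threshold = 1.5) {
  if (length(known) == 0L) stop("empty known-drug set", call. = FALSE)
  threshold <- check_scalar(threshold, "threshold", 0, 2)
  hit <- if (length(library)) max_combo(library, known) >= threshold else logical(0)
  ids <- vapply(library, `[[`, "", "drug_id")
  sort(unique(c(vapply(known, `[[`, "", "drug_id"), ids[hit])))
}

#' Filter consensus hits by chemical similarity to a reference panel
#'
#' Keeps hits whose best combo score against the reference panel reaches
#' the configured threshold, ranked by that score (descending, ties by drug
#' id).
#'
#' @param hits character vector of candidate drug ids.
#' @param descriptors named list of \code{\link{mol_descriptor}} covering
#'   every hit and every reference drug.
#' @param reference character vector of reference drug ids.
#' @param config a \code{\link{similarity_config}} (supplies
#'   \code{combo_threshold}).
#' @return \code{data.frame} with columns \code{drug_id}, \code{score} for
#'   the surviving hits, in rank order.
#' @export
similarity_filter <- function(hits, descriptors, reference,
                              config = similarity_config()) {
  stopifnot(inherits(config, "similarity_config"))
  hits <- as.character(hits)
  missing <- setdiff(c(hits, reference), names(descriptors))
  if (length(missing)) {
    stop(sprintf("missing descriptor(s) for: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (length(hits) == 0L || length(reference) == 0L) {
    return(data.frame(drug_id = character(0), score = numeric(0)))
  }
  score <- max_combo(descriptors[hits], descriptors[as.character(reference)])
  keep <- score >= config$combo_threshold
  out <- data.frame(drug_id = hits[keep], score = unname(score[keep]))
  out <- out[order(-out$score, out$drug_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read molecules and featurize them
#'
#' One molecule per line: record (SMILES or hex fingerprint), whitespace,
#' drug id.
#'
#' @param path path to the molecule file.
#' @param config a \code{\link{similarity_config}}.
#' @return named list of \code{\link{mol_descriptor}}.
#' @export
read_molecules <- function(path, config = similarity_config()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no molecules in file", call. = FALSE)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- lengths(fields) < 2L
  if (any(bad)) {
    stop(sprintf("malformed molecule line(s): %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  rec <- vapply(fields, `[[`, "", 1L)
  ids <- vapply(fields, `[[`, "", 2L)
  if (anyDuplicated(ids)) stop("duplicate drug ids in molecule file", call. = FALSE)
  if (config$scorer == "openbabel") {
    return(featurize_openbabel(rec, ids))
  }
  out <- lapply(seq_along(ids), function(i) featurize(rec[i], config, ids[i]))
  names(out) <- ids
  out
}

#' Cache descriptors to a text file
#'
#' Tab-separated: drug id, scorer, structural hex, feature hex. Exact
#' round-trip through \code{\link{read_descriptors}}.
#'
#' @param descriptors named list of \code{\link{mol_descriptor}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_descriptors <- function(descriptors, path) {
  lines <- vapply(descriptors, function(d) {
    paste(d$drug_id, d$scorer, fp_to_hex(pad4(d$fp_structural)),
          fp_to_hex(pad4(d$fp_feature)),
          length(d$fp_structural), length(d$fp_feature), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

pad4 <- function(bits) {
  pad <- (4L - length(bits) %% 4L) %% 4L
  c(bits, integer(pad))
}

#' Read a descriptor cache written by \code{\link{write_descriptors}}
#'
#' @param path path to the cache file.
#' @return named list of \code{\link{mol_descriptor}}.
#' @export
read_descriptors <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  out <- lapply(fields, function(f) {
    ns <- as.integer(f[5L]); nf <- as.integer(f[6L])
    mol_descriptor(f[1L], fp_from_hex(f[3L])[seq_len(ns)],
                   fp_from_hex(f[4L])[seq_len(nf)], f[2L])
  })
  names(out) <- vapply(out, `[[`, "", "drug_id")
  out
}
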