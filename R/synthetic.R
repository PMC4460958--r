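#' Planted low-rank drug-target network
#'
#' Generates a sparse binary interaction matrix with exact planted low-rank
#' structure: nonnegative latent factors are drawn i.i.d., and the top
#' \code{density} quantile of the score surface \eqn{U_{true} V_{true}^T}
#' defines the positive cells, so the planted rank is exact rather than
#' sampled. A seeded subset of positives is withheld as hidden true
#' associations for ranking validation, and optionally a fraction of the
#' remaining labels is flipped to emulate annotation noise.
#'
#' @param n,m numbers of drugs and targets.
#' @param D_true planted rank (<= min(n, m)).
#' @param density fraction of cells that are positive, in (0, 1].
#' @param n_hidden positives withheld from training (< n * m * density).
#' @param noise_rate fraction of training positives dropped and replaced by
#'   random false positives.
#' @param seed integer seed; the generator is a pure function of it.
#' @return a list of class \code{planted_dti}: \code{R}
#'   (\code{\link{dti_matrix}} of training positives), \code{hidden}
#'   (data.frame \code{drug}, \code{target} of withheld pairs),
#'   \code{U_true}, \code{V_true}, \code{params}.
#' @export
make_planted_dti <- function(n = 200L, m = 50L, D_true = 5L, density = 0.05,
                             n_hidden = 20L, noise_rate = 0, seed = 1L) {
  n <- check_count(n, "n"); m <- check_count(m, "m")
  D_true <- check_count(D_true, "D_true")
  density <- check_scalar(density, "density", 1e-9, 1)
  n_hidden <- check_count(n_hidden, "n_hidden", min = 0L)
  noise_rate <- check_scalar(noise_rate, "noise_rate", 0, 1)
  if (D_true > min(n, m)) stop("D_true must not exceed min(n, m)", call. = FALSE)
  if (n_hidden >= n * m * density) {
    stop("n_hidden must be smaller than the expected number of positives", call. = FALSE)
  }
  drugs <- sprintf("d%04d", seq_len(n))
  targets <- sprintf("t%04d", seq_len(m))
  with_seed(seed, {
    U <- matrix(abs(stats::rnorm(n * D_true)), n, D_true, dimnames = list(drugs, NULL))
    V <- matrix(abs(stats::rnorm(m * D_true)), m, D_true, dimnames = list(targets, NULL))
    S <- U %*% t(V)
    thr <- stats::quantile(S, 1 - density, names = FALSE)
    pos <- which(S >= thr, arr.ind = TRUE)
    dimnames(pos) <- NULL
    hid_idx <- if (n_hidden > 0L) sample(nrow(pos), n_hidden) else integer(0)
    hidden <- pos[hid_idx, , drop = FALSE]
    train <- if (length(hid_idx)) pos[-hid_idx, , drop = FALSE] else pos
    if (noise_rate > 0) {
      drop <- stats::runif(nrow(train)) < noise_rate
      n_flip <- sum(drop)
      train <- train[!drop, , drop = FALSE]
      if (n_flip > 0L) {
        used <- c(pair_keys(pos, n))
        free <- setdiff(seq_len(n * m), used)
        add <- sample(free, min(n_flip, length(free)))
        train <- rbind(train, cbind((add - 1L) %% n + 1L, (add - 1L) %/% n + 1L))
      }
    }
    structure(list(
      R = dti_matrix(drugs, targets, train),
      hidden = data.frame(drug = drugs[hidden[, 1L]],
                          target = targets[hidden[, 2L]],
                          stringsAsFactors = FALSE),
      U_true = U, V_true = V,
      params = list(n = n, m = m, D_true = D_true, density = density,
                    n_hidden = n_hidden, noise_rate = noise_rate, seed = seed)),
      class = "planted_dti")
  })
}

#' Sample evaluation negatives for a planted network
#'
#' Seeded draw of cells that are neither training positives nor hidden
#' positives, for use as the negative side of \code{\link{heldout_auc}}.
#'
#' @param planted a \code{\link{make_planted_dti}} result.
#' @param n_neg number of negative cells to draw.
#' @param seed integer seed.
#' @return data.frame with columns \code{drug}, \code{target}.
#' @export
sample_eval_negatives <- function(planted, n_neg = 200L, seed = 1L) {
  stopifnot(inherits(planted, "planted_dti"))
  n <- length(planted$R$drugs); m <- length(planted$R$targets)
  obs <- pair_keys(planted$R$pairs, n)
  hid <- (match(planted$hidden$target, planted$R$targets) - 1) * n +
    match(planted$hidden$drug, planted$R$drugs)
  free <- setdiff(seq_len(n * m), c(obs, hid))
  with_seed(seed, {
    neg <- sample(free, min(n_neg, length(free)))
    data.frame(drug = planted$R$drugs[(neg - 1L) %% n + 1L],
               target = planted$R$targets[(neg - 1L) %/% n + 1L],
               stringsAsFactors = FALSE)
  })
}

# mutate a prototype fingerprint: flip a seeded fraction of positions,
# guaranteeing at least one set bit
mutate_fp <- function(proto, mutation) {
  L <- length(proto)
  k <- round(mutation * L)
  bits <- proto
  if (k > 0L) {
    at <- sample(L, k)
    bits[at] <- 1L - bits[at]
  }
  if (sum(bits) == 0L) bits[sample(which(proto == 1L), 1L)] <- 1L
  bits
}

random_fp <- function(L, p) {
  bits <- as.integer(stats::runif(L) < p)
  if (sum(bits) == 0L) bits[sample(L, 1L)] <- 1L
  bits
}

#' Planted drug library with chemical-similarity families
#'
#' Builds a library of fingerprint descriptors organized into families:
#' each family has prototype structural and feature fingerprints, members
#' are prototypes with a seeded fraction of bits flipped (keeping the
#' expected within-family Tanimoto at or above \code{tau_in}), and
#' prototypes of different families are drawn independently (expected
#' between-family Tanimoto around the prototype-density baseline, below
#' \code{tau_out}).
#'
#' @param n_molecules library size.
#' @param n_families number of families (members assigned round-robin).
#' @param fp_length bits per fingerprint component (>= 64).
#' @param tau_in target expected within-family Tanimoto (must exceed
#'   \code{tau_out}).
#' @param tau_out ceiling on expected between-family Tanimoto.
#' @param mutation fraction of bits flipped per member; the default 0.04,
#'   with prototype density 0.3, gives expected within-family Tanimoto
#'   around 0.78 and between-family around 0.18.
#' @param prototype_density probability a prototype bit is set.
#' @param seed integer seed.
#' @return a list of class \code{planted_library}: \code{descriptors}
#'   (named list of \code{\link{mol_descriptor}}), \code{families} (named
#'   integer vector), \code{config} (the matching
#'   \code{\link{similarity_config}}), \code{params}.
#' @export
make_drug_library <- function(n_molecules = 60L, n_families = 4L,
                              fp_length = 256L, tau_in = 0.75, tau_out = 0.3,
                              mutation = 0.04, prototype_density = 0.3,
                              seed = 1L) {
  n_molecules <- check_count(n_molecules, "n_molecules")
  n_families <- check_count(n_families, "n_families")
  fp_length <- check_count(fp_length, "fp_length", min = 64L)
  if (tau_in <= tau_out) stop("tau_in must exceed tau_out", call. = FALSE)
  with_seed(seed, {
    fam <- rep(seq_len(n_families), length.out = n_molecules)
    ids <- sprintf("m%04d", seq_len(n_molecules))
    protos <- lapply(seq_len(n_families), function(f) {
      list(s = random_fp(fp_length, prototype_density),
           f = random_fp(fp_length, prototype_density))
    })
    descriptors <- lapply(seq_len(n_molecules), function(i) {
      p <- protos[[fam[i]]]
      mol_descriptor(ids[i], mutate_fp(p$s, mutation), mutate_fp(p$f, mutation),
                     "hex")
    })
    names(descriptors) <- ids
    names(fam) <- ids
    structure(list(descriptors = descriptors, families = fam,
                   config = similarity_config(fp_length = fp_length, scorer = "hex"),
                   params = list(n_molecules = n_molecules, n_families = n_families,
                                 fp_length = fp_length, tau_in = tau_in,
                                 tau_out = tau_out, mutation = mutation,
                                 prototype_density = prototype_density,
                                 seed = seed)),
              class = "planted_library")
  })
}

#' Serialize descriptors in the hex molecule-file format
#'
#' Writes one line per molecule -- the concatenated structural + feature
#' fingerprint as a hex string, whitespace, drug id -- the surrogate
#' molecule format consumed by \code{\link{read_molecules}} with the
#' \code{hex} scorer.
#'
#' @param descriptors named list of \code{\link{mol_descriptor}} with equal
#'   component lengths.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_molecules <- function(descriptors, path) {
  lines <- vapply(descriptors, function(d) {
    stopifnot(length(d$fp_structural) == length(d$fp_feature))
    paste(fp_to_hex(c(d$fp_structural, d$fp_feature)), d$drug_id)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Planted end-to-end repurposing scenario
#'
#' Couples the two planted structures so the whole pipeline is testable
#' against known ground truth. One latent family of drugs -- approved known
#' ligands of the query target, one illicit known ligand, and a few hidden
#' repurposable drugs -- shares both a latent-factor prototype (concentrated
#' on two dedicated latent dimensions that also dominate the query target's
#' factor) and a fingerprint family. The hidden drugs sit at the family
#' core (minimal latent noise): their interaction profile is
#' family-typical, their association with the query target is withheld from
#' training, and the pipeline should recover them. Decoy drugs with random
#' latent vectors and unrelated fingerprints are planted as negative
#' controls. All remaining drugs have random latent structure and are
#' grouped into unrelated fingerprint families.
#'
#' @param seed integer seed; the scenario is a pure function of it.
#' @param n_drugs,m_targets network size.
#' @param D_true planted latent dimension.
#' @param n_markers family-marker targets besides the query target: targets
#'   whose latent factor also loads on the family dimensions, so family
#'   membership is identifiable from shared associations even where the
#'   query-target association is withheld.
#' @param density fraction of positive cells.
#' @param n_known approved known ligands of the query target in the family.
#' @param n_illicit_known flagged (illicit) known ligands in the family.
#' @param n_hidden hidden repurposable family members.
#' @param n_decoys negative-control drugs.
#' @param family_noise latent perturbation of non-hidden family members.
#' @param fp_length,mutation fingerprint family parameters (see
#'   \code{\link{make_drug_library}}).
#' @return a list of class \code{planted_scenario} with the interaction
#'   matrix \code{R}, \code{hidden} pairs, drug \code{metadata},
#'   fingerprint \code{descriptors} and \code{sim_config}, the query
#'   \code{target_id}, and the planted id sets (\code{known_ids},
#'   \code{approved_known_ids}, \code{hidden_ids}, \code{decoy_ids},
#'   \code{family_ids}).
#' @export
make_planted_scenario <- function(seed = 1L, n_drugs = 60L, m_targets = 25L,
                                  D_true = 6L, n_markers = 3L,
                                  density = 0.08, n_known = 8L,
                                  n_illicit_known = 1L, n_hidden = 2L,
                                  n_decoys = 3L, family_noise = 0.25,
                                  fp_length = 256L, mutation = 0.04) {
  n_family <- n_known + n_illicit_known + n_hidden
  stopifnot(n_family + n_decoys < n_drugs, D_true >= 3L)
  drugs <- sprintf("d%04d", seq_len(n_drugs))
  targets <- sprintf("t%04d", seq_len(m_targets))
  target_id <- targets[1L]
  family_ids <- drugs[seq_len(n_family)]
  approved_known_ids <- drugs[seq_len(n_known)]
  illicit_ids <- drugs[n_known + seq_len(n_illicit_known)]
  hidden_ids <- drugs[n_known + n_illicit_known + seq_len(n_hidden)]
  decoy_ids <- drugs[(n_drugs - n_decoys + 1L):n_drugs]

  with_seed(seed, {
    # latent factors: family concentrated on dims 1:2, background on 3:D
    proto <- c(2, 2, rep(0.1, D_true - 2L))
    U <- matrix(0, n_drugs, D_true, dimnames = list(drugs, NULL))
    for (i in seq_len(n_family)) {
      noise <- if (drugs[i] %in% hidden_ids) family_noise / 4 else family_noise
      U[i, ] <- pmax(proto + noise * stats::rnorm(D_true), 0.01)
    }
    rest <- (n_family + 1L):n_drugs
    U[rest, 1:2] <- matrix(0.3 * abs(stats::rnorm(length(rest) * 2L)),
                           length(rest), 2L)
    U[rest, 3:D_true] <- matrix(abs(stats::rnorm(length(rest) * (D_true - 2L))),
                                length(rest), D_true - 2L)
    V <- matrix(abs(stats::rnorm(m_targets * D_true)), m_targets, D_true,
                dimnames = list(targets, NULL))
    V[1L, ] <- c(2, 2, rep(0.05, D_true - 2L))  # query target lives on the family dims
    for (t in seq_len(n_markers)) {            # family-marker targets
      V[1L + t, ] <- pmax(c(1.5, 1.5, rep(0.1, D_true - 2L)) +
                            0.2 * stats::rnorm(D_true), 0.01)
    }

    # rescale the query/marker factors so every planted family association
    # clears the global density threshold regardless of the background draw
    S <- U %*% t(V)
    fam_rows <- seq_len(n_family)
    mk_cols <- seq_len(1L + n_markers)
    thr0 <- stats::quantile(S[, -mk_cols], 1 - density, names = FALSE)
    fam_min <- min(S[fam_rows, mk_cols])
    if (fam_min < 1.4 * thr0) {
      V[mk_cols, ] <- V[mk_cols, , drop = FALSE] * (1.4 * thr0 / fam_min)
    }
    S <- U %*% t(V)
    thr <- stats::quantile(S, 1 - density, names = FALSE)
    pos <- which(S >= thr, arr.ind = TRUE)
    dimnames(pos) <- NULL
    # withhold the hidden family members' association with the query target
    hid_rows <- match(hidden_ids, drugs)
    is_hidden_pair <- pos[, 2L] == 1L & pos[, 1L] %in% hid_rows
    if (!all(hid_rows %in% pos[pos[, 2L] == 1L, 1L])) {
      stop("planting failed: a hidden family member is not associated with the query target",
           call. = FALSE)
    }
    train <- pos[!is_hidden_pair, , drop = FALSE]
    R <- dti_matrix(drugs, targets, train)

    # fingerprint families: family A = latent family; background families
    # for the other non-decoy drugs; independent random decoys
    protos <- list(s = random_fp(fp_length, 0.3), f = random_fp(fp_length, 0.3))
    descriptors <- vector("list", n_drugs)
    names(descriptors) <- drugs
    for (id in family_ids) {
      descriptors[[id]] <- mol_descriptor(id, mutate_fp(protos$s, mutation),
                                          mutate_fp(protos$f, mutation), "hex")
    }
    others <- setdiff(drugs, c(family_ids, decoy_ids))
    n_bg <- max(1L, length(others) %/% 12L)
    bg_fam <- rep(seq_len(n_bg), length.out = length(others))
    bg_protos <- lapply(seq_len(n_bg), function(f) {
      list(s = random_fp(fp_length, 0.3), f = random_fp(fp_length, 0.3))
    })
    for (i in seq_along(others)) {
      p <- bg_protos[[bg_fam[i]]]
      descriptors[[others[i]]] <- mol_descriptor(others[i], mutate_fp(p$s, mutation),
                                                 mutate_fp(p$f, mutation), "hex")
    }
    for (id in decoy_ids) {
      descriptors[[id]] <- mol_descriptor(id, random_fp(fp_length, 0.3),
                                          random_fp(fp_length, 0.3), "hex")
    }

    status <- rep("approved", n_drugs)
    status[match(illicit_ids, drugs)] <- "illicit"
    metadata <- drug_records(drugs, name = paste("drug", drugs), status = status)

    structure(list(
      R = R,
      hidden = data.frame(drug = hidden_ids, target = target_id,
                          stringsAsFactors = FALSE),
      metadata = metadata,
      descriptors = descriptors,
      sim_config = similarity_config(fp_length = fp_length, scorer = "hex"),
      target_id = target_id,
      known_ids = sort(known_drugs(R, target_id)),
      approved_known_ids = approved_known_ids,
      hidden_ids = hidden_ids,
      decoy_ids = decoy_ids,
      family_ids = family_ids,
      params = list(seed = seed, n_drugs = n_drugs, m_targets = m_targets,
                    D_true = D_true, density = density, n_known = n_known,
                    n_illicit_known = n_illicit_known, n_hidden = n_hidden,
                    n_decoys = n_decoys, family_noise = family_noise,
                    fp_length = fp_length, mutation = mutation)),
      class = "planted_scenario")
  })
}

#' Write a planted scenario to pipeline input files
#'
#' Emits the three files the pipeline readers consume: a tab-separated
#' interaction edge list, a drug metadata CSV, and a hex molecule file.
#'
#' @param scenario a \code{\link{make_planted_scenario}} result.
#' @param dir output directory (created if missing).
#' @return named character vector of the three paths.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "planted_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(interactions = file.path(dir, "interactions.tsv"),
             metadata = file.path(dir, "drugs.csv"),
             molecules = file.path(dir, "molecules.txt"))
  write_interactions(scenario$R, paths[["interactions"]])
  utils::write.csv(scenario$metadata, paths[["metadata"]], row.names = FALSE,
                   quote = FALSE)
  write_molecules(scenario$descriptors, paths[["molecules"]])
  paths
}
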