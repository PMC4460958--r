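#' Build a drug metadata table
#'
#' Normalizes a set of drug records to the canonical metadata table used by
#' the pipeline: id, name, regulatory status and optional SMILES. Status
#' strings outside \code{approved}, \code{illicit}, \code{withdrawn} are
#' mapped to \code{other} with a warning; downstream filtering treats only
#' \code{approved} drugs as usable.
#'
#' @param id character vector of unique drug ids.
#' @param name drug names (defaults to the ids).
#' @param status character vector of regulatory statuses.
#' @param smiles optional SMILES strings (\code{NA} where unavailable).
#' @return a \code{data.frame} with columns \code{id}, \code{name},
#'   \code{status} (factor) and \code{smiles}.
#' @export
drug_records <- function(id, name = id, status = "approved", smiles = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate drug ids in metadata", call. = FALSE)
  status <- rep_len(as.character(status), length(id))
  known <- c("approved", "illicit", "withdrawn", "other")
  bad <- !(status %in% known)
  if (any(bad)) {
    warning(sprintf("%d unrecognized status value(s) mapped to 'other': %s",
                    sum(bad), paste(unique(status[bad]), collapse = ", ")),
            call. = FALSE)
    status[bad] <- "other"
  }
  data.frame(id = id,
             name = rep_len(as.character(name), length(id)),
             status = factor(status, levels = known),
             smiles = rep_len(as.character(smiles), length(id)),
             stringsAsFactors = FALSE)
}

#' Read a drug metadata CSV
#'
#' Expects a header line with columns \code{id,name,status,smiles}
#' (\code{smiles} optional).
#'
#' @param path path to the CSV file.
#' @return a drug metadata \code{data.frame}; see \code{\link{drug_records}}.
#' @export
read_drug_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "status")
  if (!all(need %in% names(df))) {
    stop("drug metadata must have columns id, name, status", call. = FALSE)
  }
  drug_records(df$id, df$name, df$status,
               if ("smiles" %in% names(df)) df$smiles else NA_character_)
}

#' Keep only approved drugs
#'
#' Removes illicit, withdrawn and otherwise non-approved records, preserving
#' input order. This mirrors the curation step in which flagged members of a
#' known-ligand set are discarded before enrichment analysis.
#'
#' @param drugs a drug metadata \code{data.frame} (see \code{\link{drug_records}}).
#' @return the subset of rows with status \code{approved}.
#' @examples
#' d <- drug_records(c("a", "b", "c"), status = c("approved", "illicit", "approved"))
#' filter_approved(d)$id
#' @export
filter_approved <- function(drugs) {
  stopifnot(is.data.frame(drugs), all(c("id", "status") %in% names(drugs)))
  if (anyNA(drugs$status)) stop("status missing for some records", call. = FALSE)
  drugs[drugs$status == "approved", , drop = FALSE]
}

#' Combine known and predicted drug sets
#'
#' Union of the approved known-ligand set and the ensemble-predicted
#' candidate set; this union is the input universe for latent-space
#' clustering. Overlap between the two sets is reported via a message.
#'
#' @param known_approved character vector of approved known drug ids.
#' @param predicted character vector of predicted candidate drug ids.
#' @return character vector: the union, known drugs first, first-appearance
#'   order, no duplicates.
#' @export
combine_candidate_set <- function(known_approved, predicted) {
  known_approved <- unique(as.character(known_approved))
  predicted <- unique(as.character(predicted))
  overlap <- intersect(known_approved, predicted)
  if (length(overlap) > 0L) {
    message(sprintf("combine_candidate_set: %d drug(s) in both sets", length(overlap)))
  }
  union(known_approved, predicted)
}
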