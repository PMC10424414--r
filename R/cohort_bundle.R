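#' Read a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `subject_id`, `role`
#' (donor/recipient), `donor_id`, `cohort_id`, `days_post_fmt`, and optionally
#' `age`, `sex`, `weight`, `outcome`. Every recipient row must carry `donor_id`
#' and `days_post_fmt`; donor rows must carry neither.
#'
#' @param path TSV path.
#' @return A validated data frame.
#' @export
read_sample_metadata <- function(path) {
  md <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("", "NA"))
  validate_sample_metadata(md)
}

#' Validate sample metadata
#' @param md Metadata data frame.
#' @return `md` with columns coerced, or an error.
#' @export
validate_sample_metadata <- function(md) {
  need <- c("sample_id", "subject_id", "role", "cohort_id")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!"donor_id" %in% names(md)) md$donor_id <- NA_character_
  if (!"days_post_fmt" %in% names(md)) md$days_post_fmt <- NA_real_
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id in metadata", call. = FALSE)
  if (!all(md$role %in% c("donor", "recipient")))
    stop("role must be 'donor' or 'recipient'", call. = FALSE)
  rec <- md$role == "recipient"
  if (any(rec & (is.na(md$donor_id) | is.na(md$days_post_fmt))))
    stop("every recipient row needs donor_id and days_post_fmt", call. = FALSE)
  if (any(!rec & (!is.na(md$donor_id) | !is.na(md$days_post_fmt))))
    stop("donor rows must not carry donor_id or days_post_fmt", call. = FALSE)
  md
}

#' Bundle donor and recipient tables with their pairing
#'
#' A cohort bundle holds the donor feature table, the recipient feature table,
#' per-sample metadata and a pairing map (recipient sample to donor sample,
#' days post-FMT and cohort). The two tables are aligned onto the union taxon
#' axis (zero-padding missing taxa) at construction.
#'
#' @param donors,recipients `feature_table`s sharing one value space.
#' @param metadata Data frame per [validate_sample_metadata()].
#' @param pairing Data frame with columns `recipient_sample`, `donor_sample`,
#'   `days_post_fmt`, `cohort_id`. If `NULL`, derived from `metadata` by
#'   matching each recipient's `donor_id` to donor `subject_id`s.
#' @return A `cohort_bundle` object.
#' @export
cohort_bundle <- function(donors, recipients, metadata, pairing = NULL) {
  metadata <- validate_sample_metadata(metadata)
  aligned <- align_union(list(donors, recipients))
  donors <- aligned[[1L]]
  recipients <- aligned[[2L]]
  if (is.null(pairing)) {
    md_r <- metadata[metadata$role == "recipient" &
                       metadata$sample_id %in% rownames(recipients), , drop = FALSE]
    md_d <- metadata[metadata$role == "donor", , drop = FALSE]
    donor_sample <- md_d$sample_id[match(md_r$donor_id, md_d$subject_id)]
    pairing <- data.frame(recipient_sample = md_r$sample_id,
                          donor_sample = donor_sample,
                          days_post_fmt = md_r$days_post_fmt,
                          cohort_id = md_r$cohort_id,
                          stringsAsFactors = FALSE)
    pairing <- pairing[!is.na(pairing$donor_sample), , drop = FALSE]
  }
  bad <- setdiff(pairing$recipient_sample, rownames(recipients))
  if (length(bad)) stop("pairing references unknown recipient sample(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(pairing$donor_sample, rownames(donors))
  if (length(bad)) stop("pairing references unknown donor sample(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(donors = donors, recipients = recipients,
                 metadata = metadata, pairing = pairing),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(paste0("<cohort_bundle> %d donor samples, %d recipient samples, ",
                     "%d pairs, %d taxa, %d cohort(s)\n"),
              nrow(x$donors), nrow(x$recipients), nrow(x$pairing),
              ncol(x$donors), length(unique(x$pairing$cohort_id))))
  invisible(x)
}

#' Subject id of each recipient sample in the pairing
#' @param bundle A `cohort_bundle`.
#' @return Character vector parallel to `bundle$pairing` rows.
#' @export
pairing_subjects <- function(bundle) {
  md <- bundle$metadata
  md$subject_id[match(bundle$pairing$recipient_sample, md$sample_id)]
}
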