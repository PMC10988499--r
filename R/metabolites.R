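#' Construct a metabolite intensity matrix
#'
#' Samples-by-compounds non-negative intensities with a group label per
#' sample, the downstream container for LC-MS metabolomics after peak
#' picking and identification.
#'
#' @param intensities Numeric matrix or data frame, samples in rows,
#'   compounds in columns (column names = compound ids), all values >= 0.
#' @param sample_groups Character/factor group label per sample (no missing).
#' @param sample_ids Optional sample identifiers (default `S1..Sn`).
#' @return A `metabolite_matrix` object.
#' @export
metabolite_matrix <- function(intensities, sample_groups, sample_ids = NULL) {
  m <- as.matrix(intensities)
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0)) abort("intensities must be non-negative and complete")
  if (is.null(colnames(m))) colnames(m) <- paste0("compound_", seq_len(ncol(m)))
  if (length(sample_groups) != nrow(m)) {
    abort("`sample_groups` must have one label per sample (row)")
  }
  if (anyNA(sample_groups) || any(!nzchar(as.character(sample_groups)))) {
    abort("missing group labels are not allowed")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(m)))
  structure(
    list(intensities = m,
         sample_groups = as.character(sample_groups),
         sample_ids = as.character(sample_ids)),
    class = "metabolite_matrix"
  )
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %d samples x %d compounds; groups: %s\n",
              nrow(x$intensities), ncol(x$intensities),
              paste(unique(x$sample_groups), collapse = ", ")))
  invisible(x)
}

#' Read a metabolite matrix from CSV
#'
#' Layout: first column sample id, second column group label, remaining
#' columns compound intensities.
#'
#' @param path CSV path.
#' @return A [metabolite_matrix()].
#' @export
read_metabolite_matrix <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(tb) < 3) abort("metabolite CSV needs sample, group and >=1 compound column")
  m <- as.matrix(tb[, -(1:2)])
  rownames(m) <- tb[[1L]]
  metabolite_matrix(m, tb[[2L]], sample_ids = tb[[1L]])
}

#' Write a metabolite matrix to CSV
#'
#' @param mat A `metabolite_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metabolite_matrix <- function(mat, path) {
  tb <- dplyr::bind_cols(
    tibble(sample_id = mat$sample_ids, group = mat$sample_groups),
    as_tibble(mat$intensities)
  )
  write_csv_full(tb, path)
  invisible(path)
}

#' Compound and feature records for identification matching
#'
#' Tibble constructors for library compounds (theoretical mass, reference
#' retention time) and measured features (measured mass, observed retention
#' time, isotope-pattern match).
#'
#' @param theoretical_mass,measured_mass Monoisotopic mass in Da (> 0).
#' @param retention_time Retention time in seconds.
#' @param isotope_match Isotope-abundance pattern match, percent in `[0, 100]`.
#' @param compound_id Identifier.
#' @return A one-row tibble.
#' @export
compound_record <- function(compound_id, theoretical_mass, retention_time) {
  stopifnot(theoretical_mass > 0)
  tibble(compound_id = compound_id,
         theoretical_mass = theoretical_mass,
         retention_time = retention_time)
}

#' @rdname compound_record
#' @export
feature_record <- function(compound_id, measured_mass, retention_time,
                           isotope_match) {
  stopifnot(measured_mass > 0, isotope_match >= 0, isotope_match <= 100)
  tibble(compound_id = compound_id,
         measured_mass = measured_mass,
         retention_time = retention_time,
         isotope_match = isotope_match)
}
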