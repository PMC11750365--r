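#' Assay table schema and I/O
#'
#' An assay table holds one row per replicate beaker across the six
#' model-guided assay types:
#' \describe{
#'   \item{mono_1 / mono_2}{single-species density gradients (estimate
#'     `r_i`, `a_ii`)}
#'   \item{inter_1 / inter_2}{focal-species gradient against the other
#'     species held at a fixed density (estimate `a_12`, `a_21`)}
#'   \item{feed_1 / feed_2}{24 h feeding assays with and without herbivores
#'     (estimate `beta_1`, `beta_2`)}
#' }
#' Columns: `assay_type`, `replicate`, `n0`, `n_final`, `duration_days`,
#' `competitor_density` (0 if absent), `n_herbivores`, `reset_times`
#' (semicolon-separated days, may be empty).
#'
#' @param table a data.frame to validate.
#' @return The validated table (invisibly for the check).
#' @export
validate_assay_table <- function(table) {
  cols <- c("assay_type", "replicate", "n0", "n_final", "duration_days",
            "competitor_density", "n_herbivores", "reset_times")
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("assay table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok_types <- c("mono_1", "mono_2", "inter_1", "inter_2", "feed_1", "feed_2")
  bad <- setdiff(unique(table$assay_type), ok_types)
  if (length(bad))
    stop("unknown assay_type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(table$n0 <= 0)) stop("n0 must be > 0", call. = FALSE)
  if (any(table$n_final < 0)) stop("n_final must be >= 0", call. = FALSE)
  if (any(table$duration_days <= 0))
    stop("duration_days must be > 0", call. = FALSE)
  if (any(table$competitor_density < 0))
    stop("competitor_density must be >= 0", call. = FALSE)
  if (any(table$n_herbivores < 0))
    stop("n_herbivores must be >= 0", call. = FALSE)
  invisible(table)
}

#' @rdname validate_assay_table
#' @param path CSV file path.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop("assay table not found: ", path, call. = FALSE)
  tab <- read.csv(path, colClasses = list(reset_times = "character"))
  tab$reset_times[is.na(tab$reset_times)] <- ""
  validate_assay_table(tab)
  tab
}

#' @rdname validate_assay_table
#' @export
write_assay_table <- function(table, path) {
  validate_assay_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

parse_reset_times <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric())
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}
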