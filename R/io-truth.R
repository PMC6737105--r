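#' Write simulation truth to a plain-text sidecar file
#'
#' Serialises the ground-truth parameters emitted by the simulators in
#' a simple long tabular format: one row per value with columns
#' `component` (e.g. `Q`, `P`, `F`, `ne_trajectory`), `row`, `col` and
#' `value`. Scalars and vectors use `col = 1`.
#'
#' @param truth Truth list from [simulate_wf_population()] or
#'   [simulate_admixed_genotypes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  rows <- list()
  add <- function(component, m) {
    m <- as.matrix(m)
    idx <- which(!is.na(m), arr.ind = TRUE)
    rows[[length(rows) + 1L]] <<- data.frame(component = component,
                                             row = idx[, 1L],
                                             col = idx[, 2L],
                                             value = m[idx])
  }
  for (nm in names(truth)) {
    obj <- truth[[nm]]
    if (is.numeric(obj) || is.matrix(obj)) add(nm, obj)
    else if (is.data.frame(obj)) add(nm, as.matrix(obj))
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simulation-truth sidecar file
#'
#' @param path Path written by [write_sim_truth()].
#' @return Named list of numeric matrices (single-column components are
#'   returned as vectors).
#' @export
read_sim_truth <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, df$component), function(g) {
    m <- matrix(NA_real_, max(g$row), max(g$col))
    m[cbind(g$row, g$col)] <- g$value
    if (ncol(m) == 1L) as.vector(m) else m
  })
  out
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and
#' `#` comments ignored. Values are split on commas and converted to
#' numeric where possible.
#'
#' @param path Path to the configuration file.
#' @return Named list.
#' @export
read_keyvalue_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    key <- trimws(m[2L])
    vals <- trimws(strsplit(m[3L], ",")[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (all(!is.na(num))) num else vals
  }
  out
}
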