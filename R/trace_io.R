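#' Write / read a transient trace as CSV
#'
#' Plain CSV with columns `delay_ps`, `dA_mOD`; the probe frequency and
#' noise floor travel in `#`-prefixed header comments.
#'
#' @param trace A transient tibble.
#' @param path File path.
#' @return `path` invisibly (write) or a `transient_trace` tibble (read).
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pf <- attr(trace, "probe_frequency")
  ns <- attr(trace, "noise_sigma")
  writeLines(sprintf("# probe_frequency_cm1=%s", format(pf %||% NA)), con)
  writeLines(sprintf("# noise_sigma_mOD=%s", format(ns %||% NA)), con)
  writeLines("delay_ps,dA_mOD", con)
  writeLines(sprintf("%.6g,%.6g", trace$delay_ps, trace$dA_mOD), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("delay_ps", "dA_mOD") %in% names(df))) {
    stop("trace CSV must have columns delay_ps, dA_mOD", call. = FALSE)
  }
  out <- tibble::new_tibble(tibble::as_tibble(df), class = "transient_trace")
  getv <- function(key) {
    m <- hdr[grepl(key, hdr)]
    if (length(m)) suppressWarnings(as.numeric(sub(paste0(".*", key, "="),
                                                   "", m[1]))) else NA_real_
  }
  attr(out, "probe_frequency") <- getv("probe_frequency_cm1")
  attr(out, "noise_sigma") <- getv("noise_sigma_mOD")
  out
}
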