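# Delimited-text readers and writers for dispersion profiles and
# magnetization curves.  Comma-separated, UTF-8, header row with
# unit-suffixed column names; provenance (package version, seed, config
# fingerprint) embedded as leading comment lines.

.provenance_header <- function(extra = character(0)) {
  c(sprintf("# package: %s %s", "gelrelax",
            as.character(utils::packageVersion("gelrelax"))),
    extra)
}

# small deterministic polynomial-rolling fingerprint of an R object, used to
# stamp outputs with the configuration they came from
config_fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 1000000007  # exact in doubles
  sprintf("%08x", h)
}

#' Write an NMRD profile to CSV
#'
#' Columns \code{frequency_MHz}, \code{R1_per_s}, \code{rel_error}; sample
#' metadata and provenance go into leading \code{#} comment lines.
#'
#' @param profile An \code{\link{nmrd_profile}}.
#' @param path Output file path.
#' @param extra_comments Additional comment lines (already prefixed or not).
#' @return \code{path}, invisibly.
#' @export
write_nmrd_profile <- function(profile, path, extra_comments = character(0)) {
  stopifnot(inherits(profile, "nmrd_profile"))
  meta <- c(sprintf("# sample_id: %s", attr(profile, "sample_id")),
            sprintf("# temperature_C: %s", attr(profile, "temperature_C")))
  lines <- c(.provenance_header(), meta,
             sub("^([^#])", "# \\1", extra_comments))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(
    data.frame(frequency_MHz = profile$frequency_Hz / 1e6,
               R1_per_s = profile$R1, rel_error = profile$rel_error),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an NMRD profile from CSV
#'
#' @param path File as written by \code{\link{write_nmrd_profile}}.
#' @return An \code{\link{nmrd_profile}}.
#' @export
read_nmrd_profile <- function(path) {
  hdr <- readLines(path, n = 20)
  hdr <- hdr[startsWith(hdr, "#")]
  pick <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frequency_MHz", "R1_per_s", "rel_error")
  if (!all(need %in% names(df)))
    stop("profile file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  nmrd_profile(mhz_to_hz(df$frequency_MHz), df$R1_per_s, df$rel_error,
               sample_id = pick("sample_id"),
               temperature_C = as.numeric(pick("temperature_C")))
}

#' Write a magnetization curve to CSV
#'
#' Columns \code{time_s}, \code{amplitude}; the sequence tag and provenance
#' are embedded as comment lines.
#'
#' @param curve A \code{\link{magnetization_curve}}.
#' @param path Output file path.
#' @param extra_comments Additional comment lines.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(curve, path, extra_comments = character(0)) {
  stopifnot(inherits(curve, "magnetization_curve"))
  sp <- attr(curve, "spec")
  lines <- c(.provenance_header(),
             sprintf("# sequence: %s", sp$sequence),
             sprintf("# echo_time_s: %s", sp$echo_time_s),
             sub("^([^#])", "# \\1", extra_comments))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(data.frame(time_s = curve$time_s,
                                amplitude = curve$amplitude),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a magnetization curve from CSV
#'
#' @param path File as written by \code{\link{write_curve}}.
#' @return A \code{\link{magnetization_curve}}.
#' @export
read_curve <- function(path) {
  hdr <- readLines(path, n = 20)
  hdr <- hdr[startsWith(hdr, "#")]
  seq_ln <- grep("^# sequence:", hdr, value = TRUE)
  sequence <- if (length(seq_ln)) trimws(sub("^# sequence:", "", seq_ln[1]))
  else "CPMG"
  echo_ln <- grep("^# echo_time_s:", hdr, value = TRUE)
  echo <- if (length(echo_ln))
    as.numeric(trimws(sub("^# echo_time_s:", "", echo_ln[1]))) else 100e-6
  df <- utils::read.csv(path, comment.char = "#")
  sp <- acq_spec(sequence, n_points = nrow(df), echo_time_s = echo,
                 n_echoes = nrow(df))
  magnetization_curve(df$time_s, df$amplitude, sp)
}
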