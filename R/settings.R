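#' Pipeline settings
#'
#' All tunable parameters of the pipeline with their defaults:
#' E-value cutoff 1e-3 for the similarity search, at least 4 orthologs per
#' retained group, upstream window of 50-350 bp, transcription-unit gap
#' threshold bound to the minimum upstream length unless set independently,
#' the gene itself as upstream representative, a fixed-length upstream
#' window, and at least 2 members per written cluster file.
#'
#' @param evalue_cutoff Retain hits with E-value at or below this (> 0).
#' @param min_orthologs Minimum reference genomes with an ortholog (>= 1);
#'   the target gene does not count.
#' @param min_up_length Minimum upstream length in bp (> 0).
#' @param max_up_length Maximum upstream length in bp (>= `min_up_length`).
#' @param tu_gap_threshold Intergenic distance splitting transcription
#'   units; defaults to `min_up_length`.
#' @param representative_mode `"gene-self"` (extract each gene's own
#'   upstream, excluding short ones) or `"tu-leader"` (operon-internal genes
#'   map to their unit leader's upstream).
#' @param window_mode `"fixed-window"` or `"intergenic-only"`, see
#'   [extract_upstream()].
#' @param min_members Minimum members for a cluster file to be written.
#' @return An object of class `pipeline_settings`.
#' @export
default_settings <- function(evalue_cutoff = 1e-3,
                             min_orthologs = 4L,
                             min_up_length = 50L,
                             max_up_length = 350L,
                             tu_gap_threshold = min_up_length,
                             representative_mode = c("gene-self", "tu-leader"),
                             window_mode = c("fixed-window", "intergenic-only"),
                             min_members = 2L) {
  s <- structure(
    list(evalue_cutoff = as.numeric(evalue_cutoff),
         min_orthologs = as.integer(min_orthologs),
         min_up_length = as.integer(min_up_length),
         max_up_length = as.integer(max_up_length),
         tu_gap_threshold = as.integer(tu_gap_threshold),
         representative_mode = match.arg(representative_mode),
         window_mode = match.arg(window_mode),
         min_members = as.integer(min_members)),
    class = "pipeline_settings"
  )
  validate_settings(s)
}

validate_settings <- function(s) {
  fail <- function(key, why) stop("invalid setting '", key, "': ", why)
  if (is.na(s$evalue_cutoff) || s$evalue_cutoff <= 0) {
    fail("evalue_cutoff", "must be > 0")
  }
  if (is.na(s$min_orthologs) || s$min_orthologs < 1L) {
    fail("min_orthologs", "must be >= 1")
  }
  if (is.na(s$min_up_length) || s$min_up_length <= 0L) {
    fail("min_up_length", "must be > 0")
  }
  if (is.na(s$max_up_length) || s$max_up_length < s$min_up_length) {
    fail("max_up_length", "must be >= min_up_length")
  }
  if (is.na(s$tu_gap_threshold) || s$tu_gap_threshold < 0L) {
    fail("tu_gap_threshold", "must be >= 0")
  }
  if (is.na(s$min_members) || s$min_members < 1L) {
    fail("min_members", "must be >= 1")
  }
  s
}

#' @export
print.pipeline_settings <- function(x, ...) {
  cat("<pipeline_settings>\n")
  for (k in names(x)) cat("  ", format(k, width = 20), x[[k]], "\n", sep = "")
  invisible(x)
}

# settings.txt key aliases -> canonical names; legacy keys that configured
# the original tool's runtime are recognised and ignored
SETTINGS_ALIASES <- c(
  e_value = "evalue_cutoff", evalue = "evalue_cutoff",
  e_value_cutoff = "evalue_cutoff", evalue_cutoff = "evalue_cutoff",
  orthologs_count = "min_orthologs", ortholog_count = "min_orthologs",
  min_orthologs = "min_orthologs",
  min_up_length = "min_up_length", min_up = "min_up_length",
  max_up_length = "max_up_length", max_up = "max_up_length",
  tu_gap_threshold = "tu_gap_threshold",
  representative_mode = "representative_mode",
  window_mode = "window_mode",
  min_members = "min_members"
)
SETTINGS_IGNORED <- c("configuration", "gnu_path", "gnu_on_windows_path", "path_of_gnu")

#' Read a key=value settings file
#'
#' Lines of the form `key = value`; `#` starts a comment and blank lines are
#' skipped. Keys are normalised to lowercase snake_case, legacy labels (e.g.
#' `E_value`, `Orthologs_count`, `Max_UP_length`, `Min_UP_length`) are
#' accepted as aliases, the legacy machine-configuration keys are recognised
#' and ignored, and unknown keys raise a warning. Missing keys take the
#' defaults of [default_settings()]; an unparsable value or an invariant
#' violation is fatal and names the offending key.
#'
#' @param path Path to the settings file.
#' @return A `pipeline_settings` object.
#' @export
load_settings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1L]]
    if (length(kv) != 3L) {
      stop("unparsable settings line: '", ln, "' (expected key=value)")
    }
    key <- gsub("[^a-z0-9]+", "_", tolower(trimws(kv[2L])))
    val <- trimws(kv[3L])
    if (key %in% SETTINGS_IGNORED) next
    canon <- SETTINGS_ALIASES[key]
    if (is.na(canon)) {
      warning("unknown settings key '", trimws(kv[2L]), "' ignored")
      next
    }
    vals[[canon]] <- val
  }
  s <- default_settings()
  numeric_keys <- c("evalue_cutoff", "min_orthologs", "min_up_length",
                    "max_up_length", "tu_gap_threshold", "min_members")
  for (k in names(vals)) {
    if (k %in% numeric_keys) {
      v <- suppressWarnings(as.numeric(vals[[k]]))
      if (is.na(v)) stop("invalid setting '", k, "': '", vals[[k]],
                         "' is not a number")
      s[[k]] <- if (k == "evalue_cutoff") v else as.integer(v)
    } else {
      s[[k]] <- vals[[k]]
    }
  }
  if (!s$representative_mode %in% c("gene-self", "tu-leader")) {
    stop("invalid setting 'representative_mode': '", s$representative_mode, "'")
  }
  if (!s$window_mode %in% c("fixed-window", "intergenic-only")) {
    stop("invalid setting 'window_mode': '", s$window_mode, "'")
  }
  # unless set explicitly, the TU threshold follows min_up_length
  if (is.null(vals$tu_gap_threshold)) s$tu_gap_threshold <- s$min_up_length
  validate_settings(s)
}
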