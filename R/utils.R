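# internal helpers shared across modules

# split a line on any run of spaces/tabs, dropping leading/trailing blanks
split_ws <- function(line) {
  toks <- strsplit(trimws(line), "[ \t]+")[[1]]
  toks[nzchar(toks)]
}

# numeric conversion where "NaN"/"nan"/"NA"/"." become NA_real_ without warning
as_numeric_na <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[x %in% c("NaN", "nan", "NA", "na", ".")] <- NA_real_
  out
}

is_numeric_token <- function(x) {
  !is.na(suppressWarnings(as.numeric(x))) | x %in% c("NaN", "nan")
}

# read non-empty lines of a text file, preserving original line numbers
read_data_lines <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Validate a display color
#'
#' Accepts hex `"#RRGGBB"` (optionally with alpha) or any name known to
#' [grDevices::colors()].  Invalid colors produce a warning and fall back
#' to the supplied default rather than failing.
#'
#' @param color Color string to validate.
#' @param default Fallback used when `color` is invalid.
#' @return A valid color string.
#' @export
validate_color <- function(color, default = "grey40") {
  if (is.null(color) || length(color) == 0L || is.na(color) || !nzchar(color))
    return(default)
  ok <- tryCatch({ grDevices::col2rgb(color); TRUE }, error = function(e) FALSE)
  if (!ok) {
    warning("invalid color '", color, "'; using default '", default, "'")
    return(default)
  }
  color
}
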