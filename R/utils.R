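#' @importFrom rlang abort .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows filter mutate select %>%
NULL

# Condition helpers: every error the package raises carries a class so
# callers (and the CLI) can dispatch without matching message text.
rw_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(paste0("rw_", class), "rw_error"), ...)
}

#' Read a properties-style file
#'
#' Parses simple `key=value` lines; `#` starts a comment, blank lines are
#' skipped. Later keys override earlier ones.
#'
#' @param path Path to the file.
#' @param text Character vector of lines, as an alternative to `path`.
#' @return Named character vector of values.
#' @keywords internal
read_properties <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else
    unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- character(0)
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) {
      rw_abort("parse_error", paste0("not a key=value line: '", ln, "'"))
    }
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    out[[key]] <- val
  }
  out
}

# Path to a file shipped under inst/, erroring if absent.
rw_system_file <- function(...) {
  p <- system.file(..., package = "releasewise")
  if (!nzchar(p)) {
    rw_abort("config_error",
             paste0("missing installed file: ", file.path(...)))
  }
  p
}

#' Default version-rules file shipped with the package
#' @return Path to the reference rules file.
#' @export
default_rules_path <- function() {
  rw_system_file("config", "version_rules.properties")
}

#' Default template directory shipped with the package
#' @return Path to the root of the mapping-set template tree.
#' @export
default_templates_path <- function() {
  rw_system_file("templates", "schema")
}
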