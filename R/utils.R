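# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Signal a validation error carrying a structured condition class so callers
# (and the CLI) can distinguish bad input (exit 1) from runtime failure (2).
ecx_stop <- function(..., class = "ecx_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "ecx_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

ecx_warn <- function(..., class = "ecx_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate expr under a local RNG seed without disturbing the caller's
# RNG stream (generator determinism must not leak into user sessions).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    ecx_stop("seed must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    ecx_stop(name, " must be a single non-missing number")
  }
  if (x < lo || x > hi) {
    ecx_stop(name, " = ", format(x), " outside allowed range [",
             format(lo), ", ", format(hi), "]")
  }
  invisible(x)
}

# Lines beginning "# " carry run metadata (version, seed, parameters) in all
# CSV outputs; readers must skip them.
ecx_metadata_header <- function(seed = NULL, extra = character()) {
  c(
    paste0("# ecoclimex ", as.character(utils::packageVersion("ecoclimex"))),
    paste0("# created ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (!is.null(seed)) paste0("# seed ", format(seed)),
    if (length(extra)) paste0("# ", extra)
  )
}

write_csv_with_header <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
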