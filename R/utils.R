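# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Format p-values for report tables
#'
#' Prints to four decimals with a display floor, so very small p-values are
#' rendered as `"<0.0001"` rather than zero.
#'
#' @param p numeric vector of p-values.
#' @param digits decimals to print.
#' @param floor smallest value printed exactly.
#' @return Character vector.
#' @export
format_pvalue <- function(p, digits = 4, floor = 1e-4) {
  out <- ifelse(is.na(p), NA_character_,
                ifelse(p < floor, paste0("<", format(floor, scientific = FALSE)),
                       formatC(p, digits = digits, format = "f")))
  out
}
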