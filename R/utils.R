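# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores (or removes) `.Random.seed` afterwards so that seeded phantom
#' generation never perturbs the caller's RNG stream.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-subject seed from a master seed, keeping within 32-bit range.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1000003 + i * 7919) %% .Machine$integer.max)
}

nq_stop <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "neuroquant_error")))
}

nq_log <- function(..., verbose = getOption("neuroquant.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[neuroquant] ", ...)
  invisible(NULL)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Format a 3-vector for messages.
fmt3 <- function(x) paste0("(", paste(signif(x, 4), collapse = ", "), ")")
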