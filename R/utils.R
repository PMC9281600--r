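# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
#' state afterwards.
#' @noRd
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Deterministic 31-bit hash of a string, for deriving per-cell RNG seeds.
#' @noRd
string_seed <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Coerce an expression matrix (dense or Matrix sparse) to base dense.
#' @noRd
as_dense <- function(x) {
  if (is.matrix(x)) x else as.matrix(x)
}

#' Check a genes-by-cells expression matrix: numeric, dimnames present.
#' @noRd
check_expression_matrix <- function(x, require_names = TRUE) {
  if (!(is.matrix(x) || methods::is(x, "Matrix"))) {
    stop("expected a genes x cells matrix (base matrix or Matrix)",
         call. = FALSE)
  }
  if (require_names && (is.null(rownames(x)) || is.null(colnames(x)))) {
    stop("expression matrix must carry gene rownames and cell colnames",
         call. = FALSE)
  }
  invisible(x)
}

#' stopifnot-style scalar checks with readable messages.
#' @noRd
check_scalar <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < min || x > max) {
    stop(sprintf("`%s` must be in [%s, %s]", name, format(min), format(max)),
         call. = FALSE)
  }
  if (integerish && x != round(x)) {
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  }
  invisible(x)
}
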