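#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards. Every stochastic code path in the package goes
#' through this helper, so identical seeds give bit-identical results
#' without side effects on the session RNG.
#'
#' @param seed integer seed (`NULL` for no re-seeding).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Scalar validators used by the configuration constructors; errors always
# name the offending field so misconfiguration is diagnosable from the
# message alone.
check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("field '%s' must be a single finite number", field),
         call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("field '%s' must be an integer", field), call. = FALSE)
  }
  if (strict_lower) {
    if (x <= lower) {
      stop(sprintf("field '%s' must be > %s", field, lower), call. = FALSE)
    }
  } else if (x < lower) {
    stop(sprintf("field '%s' must be >= %s", field, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("field '%s' must be <= %s", field, upper), call. = FALSE)
  }
  invisible(x)
}

# Banker's rounding to an integer count (R's round() already rounds
# half to even); isolated here so split arithmetic has one home.
round_half_even <- function(x) as.integer(round(x))

# Largest-remainder apportionment of `total` over ideal (real) quotas.
# Deterministic: ties broken by lower index. Used for stratified splits.
apportion <- function(quotas, total) {
  base <- floor(quotas)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- quotas - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    frac <- quotas - base
    ord <- order(frac, seq_along(frac))
    k <- -rem
    base[ord[seq_len(k)]] <- base[ord[seq_len(k)]] - 1
  }
  as.integer(base)
}

# Stable content hash for manifests: serialize to a temp file, md5 it.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
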