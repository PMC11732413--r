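#' @keywords internal
"_PACKAGE"

# Stable 32-bit string hash (FNV-1a) used to derive per-session RNG seeds and
# to fingerprint pipeline configurations. Pure integer arithmetic on doubles so
# the result is identical across platforms.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h)
}

#' Derive a reproducible per-session seed from a master seed
#'
#' Each sampling session gets its own RNG stream so that a single session can
#' be re-analysed in isolation (same null distribution) without replaying the
#' whole dataset. The seed combines the master seed with a hash of the
#' session's identity.
#'
#' @param master_seed Integer master seed.
#' @param site_id Site label.
#' @param week Week number.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_session_seed <- function(master_seed, site_id, week) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- fnv1a_hash(c(as.character(site_id), as.character(week)))
  as.integer((as.numeric(master_seed) + as.numeric(h)) %% 2^31)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("trapsocial_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
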