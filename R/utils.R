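# Internal helpers: classed errors, deterministic seed substreams, config hash.

ff_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "forcefluct_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x)))
    ff_stop(sprintf("`%s` must be a single finite number", name),
            "forcefluct_invalid_argument")
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    ff_stop(sprintf("`%s` must be TRUE or FALSE", name),
            "forcefluct_invalid_argument")
  invisible(x)
}

# 32-bit multiply-modulo without overflow: doubles stay below 2^53.
mulmod32 <- function(a, b) {
  lo <- a %% 65536
  hi <- a %/% 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

# FNV-1a over a character string, 32-bit.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648), b) + (h %/% 2147483648) * 2147483648
    h <- mulmod32(h, 16777619)
  }
  h
}

#' Derive a named substream seed from a run seed
#'
#' All randomness in the package flows from one per-run seed; independent
#' stages (noise synthesis, cohort attributes, residuals, ...) draw from
#' named substreams so that adding a stage never perturbs another stage's
#' stream. The derived seed is always a positive integer below 2^31.
#'
#' @param seed integer run seed.
#' @param name character scalar naming the substream.
#' @param index optional non-negative integer for indexed substreams
#'   (e.g. one per replicate).
#' @return a single integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(seed, name, index = 0L) {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(index, "index")
  h <- fnv1a32(paste0(name, ":", index))
  mixed <- (h + mulmod32(abs(seed) %% 4294967296, 2654435761)) %% 2147483646
  as.integer(mixed + 1)
}

# Short deterministic hash of an R object (used for output-file headers).
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "")
  sprintf("%08x", as.integer(fnv1a32(s) %% 2147483648))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
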