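#' @keywords internal
"_PACKAGE"

# All randomness in the package flows through named substreams derived from one
# master seed, so that independent stages (splitting, CV folds, clustering
# restarts, generators) are reproducible yet decoupled.

# 32-bit FNV-1a over the UTF-8 bytes of a string, in double arithmetic
# (exact below 2^53).
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(as.character(s)))) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# bitwXor on doubles that may exceed .Machine$integer.max
bitwXor_dbl <- function(a, b) {
  lo_a <- a %% 2147483648; hi_a <- a %/% 2147483648
  lo_b <- b %% 2147483648; hi_b <- b %/% 2147483648
  lo <- bitwXor(as.integer(lo_a), as.integer(lo_b))
  hi <- bitwXor(as.integer(hi_a), as.integer(hi_b))
  as.numeric(lo) + as.numeric(hi) * 2147483648
}

#' Derive a reproducible substream seed from a master seed and a stream name
#'
#' @param master integer master seed.
#' @param name character stream label.
#' @param index optional integer (e.g. round number) folded into the stream.
#' @return an integer in \[1, 2^31 - 2\] suitable for [set.seed()].
#' @export
substream_seed <- function(master, name, index = 0L) {
  h <- fnv1a(paste0(name, ":", index))
  s <- (abs(as.numeric(master)) * 2654435761 + h) %% 2147483646
  as.integer(s) + 1L
}

# Evaluate expr under a temporary RNG state seeded with `seed`;
# restores the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stable short hash of an R object (used to stamp outputs with their config).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- fnv1a(s)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Contact categories in canonical order (used for feature naming and the
# deterministic ordering of correlation pruning).
CATEGORIES <- c("HB", "ARO", "IP", "APO")
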