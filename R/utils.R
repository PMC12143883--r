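#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from (seed, id) so that adding sessions
# to an experiment never perturbs the random stream of existing ones.
# FNV-1a style string hash folded into [0, 2^31 - 2].
derive_seed <- function(seed, id) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 2166136261 %% 2147483629
  for (b in utf8ToInt(paste0(as.integer(seed), "::", as.character(id)))) {
    h <- bitwXor(h, b)
    # 64-bit-safe multiply by the FNV prime, kept below 2^53 via modulo
    h <- (h * 16777619) %% 2147483629
  }
  as.integer(h %% 2147483587L) + 1L
}

# Evaluate `expr` under a local RNG state seeded from (seed, id); the
# caller's RNG state is untouched.
with_stream <- function(seed, id, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, id))
  expr
}

# Half-open interval [start, end) membership for sample times.
in_interval <- function(t, start, end) t >= start & t < end

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
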