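# Shared toy fixtures, built once per session and cached.

nv_cache_env <- function() {
  if (!exists(".nv_test_cache", envir = globalenv())) {
    assign(".nv_test_cache", new.env(parent = emptyenv()), envir = globalenv())
  }
  get(".nv_test_cache", envir = globalenv())
}

cached <- function(key, expr) {
  ce <- nv_cache_env()
  if (is.null(ce[[key]])) ce[[key]] <- force(expr)
  ce[[key]]
}

toy_speaker <- function() cached("speaker", gen_speaker("female", seed = 3))

# short deterministic parameter trajectory with mixed voicing
toy_params <- function(T = 40L, seed = 11L) {
  cached(paste0("params", T, "_", seed),
         gen_word_params(synth_trial_spec(duration_s = T / 125), seed = seed))
}

# small paired dataset reused across decoder/occlusion tests
toy_dataset <- function() {
  cached("dataset", make_dataset(
    24, mapping = gen_mapping(noise_sd = 0.1, seed = 43), seed = 42))
}

toy_ecog <- function() toy_dataset()$trials[[1L]]$ecog

# reduced-width decoder configs for contract tests
toy_decoder_cfg <- function(backbone, causal) {
  decoder_config(backbone, causal = causal, C = 12L, c0 = 6L, Dh = 12L,
                 n_heads = 2L)
}

fd_gradient <- function(fun, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (fun(xp) - fun(xm)) / (2 * h)
  }
  g
}
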