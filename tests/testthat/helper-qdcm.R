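# Shared fixtures, built once per test run.

qdcm_cache <- new.env(parent = emptyenv())

# default lookup table (fast: single master trajectory)
get_lut <- function() {
  if (is.null(qdcm_cache$lut)) qdcm_cache$lut <- build_lookup()
  qdcm_cache$lut
}

# small noiseless phantom with hand-picked truth, shared across tests
get_phantom_noiseless <- function() {
  if (is.null(qdcm_cache$ph0)) {
    truth <- list(cbf0 = c(45, 55.6, 70, 60, 30, 52),
                  dc = c(0.07, 0.092, 0.12, 0.10, 0.05, 0.085),
                  kappa = c(0.05, 0.065, 0.08, 0.06, 0.04, 0.07),
                  cvr = c(2.0, 2.4, 3.0, 2.2, 1.2, 2.6),
                  m0 = rep(1, 6))
    spec <- phantom_spec(shape = c(6, 1, 1), truth = truth, tsnr = 1e9,
                         seed = 7)
    qdcm_cache$ph0 <- synthesize_dataset(spec, get_lut())
  }
  qdcm_cache$ph0
}

# independent fixed-step Euler integration of the capillary oxygen loss
# equation: the oracle against which the adaptive solver is checked
euler_oef <- function(dc, cbf, hb = 0.143, p50 = 27.1, h = 2.8,
                      phi = 1.34, inlet = 0.95, pm = 0, n = 1e5) {
  c0 <- inlet * phi * hb
  ct <- c0
  dx <- 1 / n
  for (i in seq_len(n)) {
    p <- p50 * (ct / (phi * hb - ct))^(1 / h)
    ct <- ct - dx * (dc / cbf) * (p - pm)
    if (ct <= 0) {
      ct <- 1e-12
      break
    }
  }
  (c0 - ct) / c0
}
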