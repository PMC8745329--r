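# Shared fixtures built in code at test time.

# Two-population intensity image: background N(bg_mean, bg_sd), foreground
# N(fg_mean, fg_sd) on a random fg_frac subset of pixels.
make_bimodal_image <- function(nr = 128, nc = 128, fg_frac = 0.3,
                               bg_mean = 30, bg_sd = 5,
                               fg_mean = 180, fg_sd = 10) {
  img <- matrix(rnorm(nr * nc, bg_mean, bg_sd), nr, nc)
  n_fg <- round(fg_frac * nr * nc)
  idx <- sample.int(nr * nc, n_fg)
  img[idx] <- rnorm(n_fg, fg_mean, fg_sd)
  pmin(pmax(img, 0), 255)
}

# Exhaustive Otsu oracle: scan all 256 candidate thresholds and maximize the
# between-class variance directly from the class moments.
otsu_exhaustive <- function(img) {
  v <- as.integer(pmin(pmax(floor(img), 0), 255))
  best_t <- 0L; best_var <- -1
  for (t in 0:254) {
    bg <- v[v <= t]; fg <- v[v > t]
    if (!length(bg) || !length(fg)) next
    w0 <- length(bg) / length(v); w1 <- 1 - w0
    var_b <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (var_b > best_var) { best_var <- var_b; best_t <- t }
  }
  best_t
}

# Brute-force binary opening with a centered line element, outside pixels
# ignored (same convention as the package): erosion keeps a pixel when all
# in-image pixels under the element are set; dilation sets all in-image
# pixels under the element anchored at each set pixel.
opening_bruteforce <- function(mask, len, horizontal) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- seq.int(-((len - 1L) %/% 2L), len %/% 2L)
  ero <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- if (horizontal) rep(i, length(offs)) else i + offs
    jj <- if (horizontal) j + offs else rep(j, length(offs))
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    ero[i, j] <- as.integer(all(mask[cbind(ii[ok], jj[ok])] > 0))
  }
  dil <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- if (horizontal) rep(i, length(offs)) else i + offs
    jj <- if (horizontal) j + offs else rep(j, length(offs))
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    if (any(ero[cbind(ii[ok], jj[ok])] > 0)) dil[i, j] <- 1L
  }
  dil
}

# A single simulated-and-rendered run, shared across tests that only need
# some realistic image material.
demo_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- flow_run_config("collagen_TF", seed = 42)
      states <- simulate_kinetics(cfg)
      cache <<- list(cfg = cfg, states = states,
                     run = render_images(states, cfg, render_config(seed = 7)))
    }
    cache
  }
})
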