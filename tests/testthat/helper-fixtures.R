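# shared fixtures: all synthetic inputs are built in code at test time

default_cal <- calibration_fit()   # GL 25 <-> 0.0, GL 55 <-> 5.2 wt% Ca

# image whose bone pixels carry Gaussian-distributed calcium content
gaussian_ca_image <- function(mu, sigma, n_side, cal = default_cal,
                              seed = 1) {
  set.seed(seed)
  ca <- stats::rnorm(n_side^2, mu, sigma)
  gl <- as.integer(pmin(pmax(round(ca_to_gl(cal, pmax(ca, 0))), 0), 255))
  matrix(gl, n_side, n_side)
}

# analytic histogram object: Gaussian density discretized on the bin grid
hist_from_gaussian <- function(mu, sigma, bin_width = 0.02, span = 8) {
  nbin <- ceiling((mu + span * sigma) / bin_width)
  centers <- (seq_len(nbin) - 0.5) * bin_width
  f <- stats::dnorm(centers, mu, sigma)
  structure(
    list(bin_centers = centers, bin_edges = (0:nbin) * bin_width,
         frequencies = 100 * f / sum(f), bin_width = bin_width,
         n_pixels = NA_integer_, meta = list()),
    class = "ca_histogram")
}

# histogram with all mass in the bin containing `at`
delta_hist <- function(at, bin_width = 0.17) {
  nbin <- ceiling(at / bin_width) + 10L
  f <- numeric(nbin)
  f[floor(at / bin_width) + 1L] <- 100
  structure(
    list(bin_centers = (seq_len(nbin) - 0.5) * bin_width,
         bin_edges = (0:nbin) * bin_width,
         frequencies = f, bin_width = bin_width,
         n_pixels = NA_integer_, meta = list()),
    class = "ca_histogram")
}

# binary matrix with a filled ellipse (semi-axes in px, centered)
ellipse_image <- function(n_side, a, b, theta = 0, bg_gl = 200, fg_gl = 20) {
  img <- matrix(bg_gl, n_side, n_side)
  ctr <- n_side / 2
  for (i in seq_len(n_side)) for (j in seq_len(n_side)) {
    dx <- j - 0.5 - ctr; dy <- i - 0.5 - ctr
    u <- cos(theta) * dx + sin(theta) * dy
    v <- -sin(theta) * dx + cos(theta) * dy
    if ((u / a)^2 + (v / b)^2 <= 1) img[i, j] <- fg_gl
  }
  img
}

# printed clinical values of the worked example (two males with an SGMS2
# nonsense mutation) and the reported standardized differences
patient_meta <- list(patient1 = list(sex = "M", age = 61),
                     patient2 = list(sex = "M", age = 29))
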