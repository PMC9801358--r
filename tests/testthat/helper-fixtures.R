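# Shared fixtures, all generated in code.

# A small, fully observed study configuration (no missing outcomes, no tiny
# tracts) for tests that need every generated tract to survive filtering.
clean_config <- function(n = 120, seed = 1, ...) {
  sim_config(n_tracts = n, seed = seed, small_tract_rate = 0,
             missing_rate = 0, ...)
}

# Rook-adjacency row-standardized weights on an nr x nc grid, built by hand
# (independent of knn_weights) for exact checkerboard tests.
rook_weights <- function(nr, nc) {
  n <- nr * nc
  idx <- function(r, c) (r - 1L) * nc + c
  nb <- vector("list", n)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      js <- c(if (r > 1) idx(r - 1L, c), if (r < nr) idx(r + 1L, c),
              if (c > 1) idx(r, c - 1L), if (c < nc) idx(r, c + 1L))
      nb[[idx(r, c)]] <- sort(js)
    }
  }
  w <- lapply(nb, function(js) rep(1 / length(js), length(js)))
  structure(list(ids = as.character(seq_len(n)), neighbors = nb, weights = w,
                 row_standardized = TRUE, k = NA_integer_),
            class = "spatial_weights")
}

# Power-law pmf on {2,3,4}: k^-alpha normalized.
powerlaw_pmf <- function(alpha) {
  w <- (2:4)^(-alpha)
  w / sum(w)
}

# A design + outcome where a west/east split drives different features.
split_signal_data <- function(n = 800, seed = 1) {
  withr::with_seed(seed, {
    coords <- tibble::tibble(x = runif(n, 0, 10), y = runif(n, 0, 10))
    design <- tibble::tibble(A = rnorm(n), B = rnorm(n), C = rnorm(n))
    west <- coords$x < 5
    y <- ifelse(west, 2 * design$A, 2 * design$B) + rnorm(n, 0, 0.5)
    list(design = design, coords = coords, outcome = y, west = west)
  })
}
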