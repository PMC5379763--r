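## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

## small clean single-colony movie (no noise/blur) with a few divisions
fix_clean_movie <- function() fixture("clean_movie", function() {
  simulate_movie(sim_params(seed = 11, n_founders = 1, n_frames = 16,
                            field_px = c(220, 220), noise_sigma = 0,
                            psf_sigma = 0, illumination_gradient = 0))
})

## realistic small movie: noise, blur, gradient, 1 founder
fix_noisy_movie <- function() fixture("noisy_movie", function() {
  simulate_movie(sim_params(seed = 5, n_founders = 1, n_frames = 14,
                            field_px = c(220, 220)))
})

## three separated colonies, moderate length
fix_three_colony_movie <- function() fixture("three_colony", function() {
  simulate_movie(sim_params(seed = 3, n_founders = 3, n_frames = 10,
                            field_px = c(300, 300)))
})

default_species <- function(modality = "phase-contrast")
  species_config(cell_length = 3.5, cell_width = 1.1, cal_factor = 0.125,
                 modality = modality)

## a discretized horizontal spherocylinder mask centred in an r x c field
rod_mask <- function(nr = 40, nc = 80, len = 60, wid = 9,
                     cr = NULL, cc = NULL) {
  cr <- cr %||% ((nr + 1) / 2); cc <- cc %||% ((nc + 1) / 2)
  half <- (len - wid) / 2
  m <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    t <- clamp(c - (cc - half), 0, 2 * half)
    d <- sqrt((r - cr)^2 + (c - (cc - half) - t)^2)
    m[r, c] <- d <= wid / 2
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## two horizontal spherocylinders joined end-to-end with a septum waist
bowtie_mask <- function(nr = 40, nc = 110, len = 45, wid = 11, depth = 0.65) {
  m1 <- rod_mask(nr, nc, len, wid, cc = (nc / 2) - len / 2 + wid / 2)
  m2 <- rod_mask(nr, nc, len, wid, cc = (nc / 2) + len / 2 - wid / 2)
  m <- m1 | m2
  ## carve the waist at the junction column
  jc <- round(nc / 2)
  keep_half <- depth * wid / 2
  for (c in (jc - 1):(jc + 1))
    for (r in 1:nr)
      if (m[r, c] && abs(r - (nr + 1) / 2) > keep_half) m[r, c] <- FALSE
  m
}
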