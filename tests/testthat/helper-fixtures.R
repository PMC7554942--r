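# shared fixture builders and independent oracles

default_cal <- calibration()

# logical disk mask of radius r_px centred at (cy, cx)
disk_mask <- function(nr, nc, cy, cx, r_px) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - cy)^2 + (cc - cx)^2 <= r_px^2
}

# region set where all tissue is one named region (plus optional portal)
uniform_regions <- function(nr, nc, region = "rps", cal = default_cal,
                            portal = matrix(FALSE, nr, nc)) {
  tissue <- matrix(TRUE, nr, nc)
  empty <- matrix(FALSE, nr, nc)
  periportal <- if (region == "periportal") tissue & !portal else empty
  rps <- if (region == "rps") tissue & !portal else empty
  structure(list(portal = portal, periportal = periportal, rps = rps,
                 tissue = tissue, calibration = cal,
                 periportal_margin_um = 100),
            class = "qfib_regions")
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# brute-force two-sided Wilcoxon rank-sum p-value: enumerate every
# assignment of the pooled values to group x and count assignments whose
# rank sum is at least as far from its null mean as the observed one
enumerate_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  combos <- utils::combn(n, nx)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# a hand-built fiber table row
fiber_row <- function(region, area_um2, length_um,
                      cfg = morphometry_config()) {
  width <- area_um2 / length_um
  data.frame(fiber_id = NA_integer_, pixel_count = NA_integer_,
             area_um2 = area_um2, length_um = length_um, width_um = width,
             region = region,
             is_long = length_um >= cfg$long_length_um,
             is_thick = width >= cfg$thick_width_um,
             is_aggregated = area_um2 >= cfg$aggregated_component_area_um2)
}

# slide with given shg/tpef matrices at default calibration
make_slide <- function(shg, tpef = NULL, cal = default_cal) {
  if (is.null(tpef)) tpef <- matrix(1, nrow(shg), ncol(shg))
  dual_channel_slide(shg, tpef, cal, sample_id = "fixture")
}
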