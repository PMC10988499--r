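# Shared fixtures, built in code at test time.

# uniform-random capillary map with distinct sites
random_map <- function(n, w = 200, h = 200, seed = 1) {
  set.seed(seed)
  capillary_map(tibble::tibble(x_um = runif(n, 0, w), y_um = runif(n, 0, h)),
                frame_width = w, frame_height = h)
}

# a square fibre polygon centred at (cx, cy)
square_fibre <- function(cx, cy, side) {
  s <- side / 2
  tibble::tibble(x = cx + c(-s, s, s, -s), y = cy + c(-s, -s, s, s))
}

# radial-bin comparison of a disc solve against the Krogh-Erlang profile;
# returns the maximum relative discrepancy (percent) over 1-um bins
krogh_profile_error <- function(field, R, params, r_min = 3) {
  tb <- tidy(field)
  tb$r <- sqrt(tb$x_um^2 + tb$y_um^2)
  tb <- tb[!tb$lumen & tb$r >= r_min & tb$r <= R - 0.5, ]
  tb$bin <- floor(tb$r)
  obs <- tapply(tb$po2_mmHg, tb$bin, mean)
  ref <- krogh_erlang_reference(as.numeric(names(obs)) + 0.5, R, params)
  max(abs(obs - ref) / ref) * 100
}
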