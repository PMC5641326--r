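# Independent scalar oracles used to cross-check the vectorized
# implementations. Deliberately written as plain per-element loops with their
# own formulations, not shared code paths.

# scalar HSI for one pixel; hue via grDevices::rgb2hsv (independent path)
oracle_hsi <- function(r, g, b) {
  hue <- grDevices::rgb2hsv(r, g, b, maxColorValue = 255)["h", 1] * 360
  i <- (r + g + b) / (3 * 255)
  s <- if (i > 0) 1 - min(r, g, b) / 255 / i else 0
  c(hue = unname(hue), saturation = s, intensity = i)
}

# scalar sRGB -> Lab / Luv, written independently (explicit loops/branches)
oracle_lab_luv <- function(r, g, b) {
  chan <- c(r, g, b) / 255
  lin <- numeric(3)
  for (k in 1:3) {
    lin[k] <- if (chan[k] <= 0.04045) chan[k] / 12.92 else
      ((chan[k] + 0.055) / 1.055)^2.4
  }
  X <- 0.4124564 * lin[1] + 0.3575761 * lin[2] + 0.1804375 * lin[3]
  Y <- 0.2126729 * lin[1] + 0.7151522 * lin[2] + 0.0721750 * lin[3]
  Z <- 0.0193339 * lin[1] + 0.1191920 * lin[2] + 0.9503041 * lin[3]
  wn <- c(0.4124564 + 0.3575761 + 0.1804375,
          0.2126729 + 0.7151522 + 0.0721750,
          0.0193339 + 0.1191920 + 0.9503041)  # XYZ of RGB (1,1,1)
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t * (29 / 6)^2 / 3 + 4 / 29
  L <- 116 * f(Y / wn[2]) - 16
  a <- 500 * (f(X / wn[1]) - f(Y / wn[2]))
  bb <- 200 * (f(Y / wn[2]) - f(Z / wn[3]))
  den <- X + 15 * Y + 3 * Z
  upr <- if (den > 0) 4 * X / den else 0
  vpr <- if (den > 0) 9 * Y / den else 0
  wden <- wn[1] + 15 * wn[2] + 3 * wn[3]
  u <- 13 * L * (upr - 4 * wn[1] / wden)
  v <- 13 * L * (vpr - 9 * wn[2] / wden)
  c(L = L, a = a, b = bb, u = u, v = v)
}

# scalar evaluation of each spectral index straight off its printed formula;
# takes a named vector of band reflectances keyed by wavelength
oracle_spectral <- function(bv, L = 0.5) {
  R <- function(wl) unname(bv[as.character(wl)])
  tcari <- 3 * ((R(700) - R(670)) - 0.2 * (R(700) - R(550)) * (R(700) / R(670)))
  osavi <- 1.16 * (R(780) - R(670)) / (R(780) + R(670) + 0.16)
  c(NDVI = (R(840) - R(670)) / (R(840) + R(670)),
    PRI = (R(550) - R(570)) / (R(550) + R(570)),
    SAVI = (R(840) - R(670)) / (R(840) + R(670) + L) * (1 + L),
    MCARI = ((R(700) - R(670)) - 0.2 * (R(700) - R(550))) * (R(700) / R(670)),
    WBI = R(900) / R(950),
    RDVI = (R(840) - R(670)) / sqrt(R(840) + R(670)),
    EVI = 2.5 * (R(840) - R(670)) / (R(840) + 6 * R(670) - 7.5 * R(450) + 1),
    ARI2 = R(840) * (1 / R(550) - 1 / R(700)),
    CRI2 = 1 / R(550) - 1 / R(700),
    TCARI = tcari, OSAVI = osavi, TCARI_OSAVI = tcari / osavi)
}

# per-pixel loop GA/GGA oracle (no vectorization)
oracle_ga_gga <- function(image, ga_window = c(60, 180), gga_window = c(80, 180),
                          min_saturation = 0.02) {
  h <- dim(image)[1]; w <- dim(image)[2]
  n_ga <- 0; n_gga <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    px <- oracle_hsi(image[i, j, 1], image[i, j, 2], image[i, j, 3])
    if (px["saturation"] < min_saturation) next
    if (px["hue"] >= ga_window[1] && px["hue"] <= ga_window[2]) n_ga <- n_ga + 1
    if (px["hue"] >= gga_window[1] && px["hue"] <= gga_window[2]) n_gga <- n_gga + 1
  }
  c(ga = n_ga / (h * w), gga = n_gga / (h * w))
}

# brute-force LMG: average incremental R^2 over all orderings
oracle_lmg <- function(table, response, predictors) {
  r2 <- function(s) {
    f <- if (length(s) == 0) paste(response, "~ 1") else
      paste(response, "~", paste(s, collapse = " + "))
    summary(lm(as.formula(f), data = table))$r.squared
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v)) for (p in perms(v[-k])) out <- c(out, list(c(v[k], p)))
    out
  }
  shares <- setNames(numeric(length(predictors)), predictors)
  ps <- perms(predictors)
  for (ord in ps) {
    prev <- 0
    for (k in seq_along(ord)) {
      cur <- r2(ord[seq_len(k)])
      shares[ord[k]] <- shares[ord[k]] + (cur - prev)
      prev <- cur
    }
  }
  shares / length(ps)
}

# build a plot image directly from per-pixel hue lists (hsv mid-range)
image_from_hues <- function(hues, h, w, s = 0.5, v = 0.6) {
  stopifnot(length(hues) == h * w)
  cols <- grDevices::col2rgb(grDevices::hsv(hues / 360, s, v))
  img <- array(0L, dim = c(h, w, 3))
  for (k in 1:3) img[, , k] <- matrix(cols[k, ], h, w)
  img
}
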