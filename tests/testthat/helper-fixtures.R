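# shared fixtures, built in code

# a single-layer soil with round numbers for hand-computable checks
toy_soil <- function(ll15 = 0.10, dul = 0.30, sat = 0.45, kl = 0.07,
                     thickness = 300, nlay = 1) {
  s <- make_soil("loam", 60)
  s <- s[rep(1, nlay), ]
  s$thickness_mm <- rep(thickness, nlay)
  s$ll15 <- ll15; s$dul <- dul; s$sat <- sat; s$kl <- kl
  s$sw <- s$ll15
  rownames(s) <- NULL
  s
}

# constant synthetic weather: mean temperature 25 C gives 14 deg-days
flat_weather <- function(n = 365, tmax = 30, tmin = 20, radn = 20,
                         rain = 0) {
  w <- data.frame(
    date = seq(as.Date("2001-01-01"), by = "day", length.out = n),
    tmax = tmax, tmin = tmin, radn = radn, rain = rain
  )
  validate_weather(w)
}

# agreement between generated archetypes and cluster names, maximised over
# label permutations (the clusters' own names need not match the truth)
permuted_agreement <- function(truth, labels) {
  lt <- unique(labels)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  tl <- unique(truth)
  if (length(lt) > length(tl)) return(NA_real_)
  best <- 0
  for (p in perms(tl)) {
    map <- stats::setNames(p[seq_along(lt)], lt)
    best <- max(best, mean(map[labels] == truth))
  }
  best
}
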