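# Independent optical oracle: exact multi-beam (Airy) reflectance of a
# free-standing dielectric film, from the closed-form total amplitude
# r = (r12 + r23 e^{i delta}) / (1 + r12 r23 e^{i delta}) per polarisation.
airyReflectance <- function(thickness, wavelength, nFilm, nAmbient = 1,
                            incidenceDeg = 0) {
  thI <- incidenceDeg * pi / 180
  sinT <- nAmbient * sin(thI) / nFilm
  cosT <- sqrt(1 - sinT^2)
  cosI <- cos(thI)
  rs <- (nAmbient * cosI - nFilm * cosT) / (nAmbient * cosI + nFilm * cosT)
  rp <- (nFilm * cosI - nAmbient * cosT) / (nFilm * cosI + nAmbient * cosT)
  delta <- 4 * pi * nFilm * thickness * cosT / wavelength
  one <- function(r12) {
    r23 <- -r12
    e <- exp(1i * delta)
    rt <- (r12 + r23 * e) / (1 + r12 * r23 * e)
    Mod(rt)^2
  }
  (one(rs) + one(rp)) / 2
}

# Brute-force 2-means for tiny descriptor sets: exhaustive over all
# 2-partitions, returning the within-SS-optimal centres.
bruteForce2Means <- function(X) {
  n <- nrow(X)
  best <- NULL; bestSS <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    if (all(grp == 0) || all(grp == 1)) next
    c1 <- colMeans(X[grp == 0, , drop = FALSE])
    c2 <- colMeans(X[grp == 1, , drop = FALSE])
    ss <- sum(sweep(X[grp == 0, , drop = FALSE], 2, c1)^2) +
          sum(sweep(X[grp == 1, , drop = FALSE], 2, c2)^2)
    if (ss < bestSS) { bestSS <- ss; best <- rbind(c1, c2) }
  }
  best
}
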