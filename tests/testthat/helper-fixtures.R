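# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops / closed forms, independent of the package's vectorized
# implementations.

testSpec <- function(asymmetry = 0, seed = 7, heightPx = 160, widthPx = 160) {
  sectionSpec(heightPx = heightPx, widthPx = widthPx, nCartilage = 2L,
              nMuscle = 3L, epidermisThicknessPx = 5L,
              asymmetry = asymmetry, seed = seed)
}

# pixel-pair enumeration oracle for symmetry scores: walks every position of
# the two aligned halves and tallies per-class matching (both sides) and
# union (either side) counts
bruteSymmetryScores <- function(dorsal, ventral, classes = 1:5) {
  matching <- total <- setNames(numeric(length(classes)),
                                paste0("class_", classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    for (i in seq_len(nrow(dorsal))) {
      for (j in seq_len(ncol(dorsal))) {
        d <- dorsal[i, j] == cl
        v <- ventral[i, j] == cl
        if (d && v) matching[k] <- matching[k] + 1
        if (d || v) total[k] <- total[k] + 1
      }
    }
  }
  score <- ifelse(total > 0, matching / total, NA_real_)
  list(matching = matching, total = total, score = score,
       combined = if (any(total > 0)) sum(matching[total > 0]) /
                    sum(total[total > 0]) else NA_real_)
}

# direct 2-D convolution with symmetric (half-sample) reflection padding
bruteConvolve2D <- function(mat, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  H <- nrow(mat); W <- ncol(mat)
  reflect <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i
      if (i > n) i <- 2L * n + 1L - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in -kr:kr) for (b in -kc:kc) {
      acc <- acc + kernel[a + kr + 1L, b + kc + 1L] *
        mat[reflect(i + a, H), reflect(j + b, W)]
    }
    out[i, j] <- acc
  }
  out
}

# two-sided Fisher exact p by explicit enumeration over all tables with the
# observed margins, using binomial coefficients directly
bruteFisher2x2 <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- sapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  })
  pObs <- prob[support == m[1, 1]]
  min(1, sum(prob[prob <= pObs * (1 + 1e-7)]))
}

# build a SymmetryWindow directly from two aligned label halves
makeLabelWindow <- function(dorsal, ventral, scale = 4) {
  new("SymmetryWindow", dorsal = dorsal, ventral = ventral, isLabel = TRUE,
      scaleUmPerPx = scale, sampleId = "toy", windowId = "w1")
}
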