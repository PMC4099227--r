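# Independent oracles used across the suite. These deliberately use naive
# scalar loops / enumeration so they share no code path with the package.

# Mann-Whitney AUC by explicit enumeration of all (pos, neg) pairs,
# counting ties as one half.
bruteForceAUC <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) {
    if (p > q) s <- s + 1 else if (p == q) s <- s + 0.5
  }
  s / (length(pos) * length(neg))
}

# One Perona-Malik diffusion step as nested per-pixel loops over the
# 4-neighborhood with zero-flux boundaries.
scalarDiffusionStep <- function(u, kappa, lambda,
                                variant = c("exponential", "rational")) {
  variant <- match.arg(variant)
  g <- function(d) if (variant == "exponential")
    exp(-(d / kappa)^2) else 1 / (1 + (d / kappa)^2)
  h <- nrow(u); w <- ncol(u)
  out <- u
  for (r in seq_len(h)) for (c in seq_len(w)) {
    acc <- 0
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
        diff <- u[rr, cc] - u[r, c]
        acc <- acc + g(diff) * diff
      }
    }
    out[r, c] <- u[r, c] + lambda * acc
  }
  out
}

# A random integer-valued 12-bit test grid.
randomGrid <- function(h, w, lo = 0, hi = 4095) {
  matrix(sample(lo:hi, h * w, replace = TRUE), h, w)
}

# A tiny on-disk manifest + images for pipeline tests: `spec` is a
# data.frame with columns group, bone_class, mgl, sdgl (one row per case).
makeTinyStudy <- function(dir, spec, roiH = 12L, roiW = 10L, margin = 3L,
                          seed = 99L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    img <- lyticgray::renderROIImage(spec$mgl[i], spec$sdgl[i],
                                     roiH, roiW, seed = seed + i)
    full <- matrix(1000, roiH + 2 * margin, roiW + 2 * margin)
    full[margin + seq_len(roiH), margin + seq_len(roiW)] <-
      lyticgray::imagePixels(img)
    path <- file.path(dir, sprintf("case_%02d.tif", i))
    lyticgray::writeImage(lyticgray::ImageGrid(full, 12L), path)
    data.frame(image_path = path, x0 = margin, y0 = margin,
               width = roiW, height = roiH, group = spec$group[i],
               bone_class = spec$bone_class[i],
               case_id = sprintf("case_%02d", i))
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  path
}
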