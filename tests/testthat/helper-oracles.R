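# Independent brute-force oracles used to validate the vectorised operators.
# Each is a direct transliteration of the definition with explicit loops and
# shares no code with the implementation.

oracle_median_filter <- function(image, window) {
  h <- nrow(image); w <- ncol(image); r <- (window - 1) / 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      vals <- numeric(0)
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- min(max(i + di, 1), h)   # edge replication
          jj <- min(max(j + dj, 1), w)
          vals <- c(vals, image[ii, jj])
        }
      }
      out[i, j] <- median(vals)
    }
  }
  out
}

oracle_dilate <- function(mask, element) {
  h <- nrow(mask); w <- ncol(mask)
  cy <- (nrow(element) + 1) / 2; cx <- (ncol(element) + 1) / 2
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (mask[i, j] != 0) {
        for (ei in seq_len(nrow(element))) {
          for (ej in seq_len(ncol(element))) {
            if (element[ei, ej] != 0) {
              ii <- i + ei - cy; jj <- j + ej - cx
              if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) out[ii, jj] <- 1L
            }
          }
        }
      }
    }
  }
  out
}

oracle_glcm <- function(image, offset, L, symmetric, normalize) {
  C <- matrix(0, L, L)
  h <- nrow(image); w <- ncol(image)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ii <- i + offset[1]; jj <- j + offset[2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
        C[image[i, j] + 1, image[ii, jj] + 1] <- C[image[i, j] + 1, image[ii, jj] + 1] + 1
      }
    }
  }
  if (symmetric) C <- C + t(C)
  if (normalize && sum(C) > 0) C <- C / sum(C)
  C
}

oracle_conv_relu_pool <- function(image, kern, bias, pool) {
  h <- nrow(image); w <- ncol(image); k <- nrow(kern)
  oh <- h - k + 1; ow <- w - k + 1
  fm <- matrix(0, oh, ow)
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      acc <- 0
      for (a in seq_len(k)) for (b in seq_len(k)) {
        acc <- acc + kern[a, b] * image[i + a - 1, j + b - 1]
      }
      fm[i, j] <- max(0, acc + bias)
    }
  }
  ph <- oh %/% pool; pw <- ow %/% pool
  out <- matrix(0, ph, pw)
  for (i in seq_len(ph)) {
    for (j in seq_len(pw)) {
      out[i, j] <- max(fm[(i - 1) * pool + 1:pool, (j - 1) * pool + 1:pool])
    }
  }
  out
}

oracle_otsu_2thresholds <- function(counts) {
  # exhaustive pair search on a small histogram, direct sigma^2_B evaluation
  n_bins <- length(counts)
  p <- counts / sum(counts)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  mu <- sum(p * mids)
  best <- -Inf; best_pair <- c(1, 2)
  for (t1 in 1:(n_bins - 2)) {
    for (t2 in (t1 + 1):(n_bins - 1)) {
      sb <- 0
      for (seg in list(1:t1, (t1 + 1):t2, (t2 + 1):n_bins)) {
        wk <- sum(p[seg])
        if (wk > 0) sb <- sb + wk * (sum(p[seg] * mids[seg]) / wk - mu)^2
      }
      if (sb > best) { best <- sb; best_pair <- c(t1, t2) }
    }
  }
  best_pair / n_bins
}

# Adjusted Rand index between two labelings (direct pair-counting form).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Small flat RGB test image from a label matrix and a colour per label.
rgb_from_labels <- function(labels, colors) {
  h <- nrow(labels); w <- ncol(labels)
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    v <- matrix(0, h, w)
    for (k in seq_along(colors)) v[labels == k] <- colors[[k]][ch]
    px[, , ch] <- v
  }
  px
}
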