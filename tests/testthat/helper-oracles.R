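# Independent oracles used across the suite. Each is a deliberately naive
# implementation (loops, flood fill, rank statistics) kept separate from the
# code paths it checks.

# stack-based flood fill, 8-connectivity: returns list of pixel index sets
flood_fill_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || seen[r, c]) next
    stack <- list(c(r, c)); seen[r, c] <- TRUE
    px <- list()
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      px[[length(px) + 1L]] <- p
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1L] + dr; cc <- p[2L] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
    comps[[length(comps) + 1L]] <- do.call(rbind, px)
  }
  comps
}

# tight boxes (x, y, h, w), 0-based, from the flood-fill oracle
oracle_boxes <- function(mask) {
  comps <- flood_fill_components(mask)
  if (length(comps) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      h = numeric(0), w = numeric(0)))
  out <- do.call(rbind, lapply(comps, function(px)
    data.frame(x = min(px[, 2L]) - 1, y = min(px[, 1L]) - 1,
               h = diff(range(px[, 1L])) + 1, w = diff(range(px[, 2L])) + 1)))
  out[order(out$x, out$y), , drop = FALSE]
}

# midrank Mann-Whitney AUC
auc_midrank <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# literal per-pixel double loop for PCM refinement
oracle_refine <- function(cams, features, theta, eps = 1e-8) {
  d <- dim(cams)
  n <- d[1L] * d[2L]
  x <- matrix(features, n, dim(features)[3L])
  e <- x %*% theta
  y <- matrix(cams, n, d[3L])
  out <- matrix(0, n, d[3L])
  for (i in seq_len(n)) {
    wrow <- numeric(n)
    for (j in seq_len(n)) {
      cs <- sum(e[i, ] * e[j, ]) /
        (max(sqrt(sum(e[i, ]^2)), eps) * max(sqrt(sum(e[j, ]^2)), eps))
      wrow[j] <- max(cs, 0)
    }
    s <- sum(wrow)
    if (s < eps) { out[i, ] <- y[i, ] } else out[i, ] <- (wrow / s) %*% y
  }
  array(out, d)
}

# literal elementwise weighted BCE (per-sample class sum, batch mean)
oracle_weighted_bce <- function(probs, labels, beta_p, beta_n, eps = 1e-7) {
  tot <- 0
  for (b in seq_len(nrow(probs))) {
    for (c in seq_len(ncol(probs))) {
      f <- min(max(probs[b, c], eps), 1 - eps)
      y <- labels[b, c]
      tot <- tot + (-beta_p[c] * y * log(f) - beta_n[c] * (1 - y) * log(1 - f))
    }
  }
  tot / nrow(probs)
}

make_tiny_model <- function(n_classes = 3L, seed = 1L, ...) {
  assemble_multires_model("tiny", n_classes = n_classes, seed = seed,
                          pcm_embed = 8L, ...)
}

random_box <- function(side) {
  h <- sample(3:(side %/% 2), 1L); w <- sample(3:(side %/% 2), 1L)
  c(x = sample(0:(side - w), 1L), y = sample(0:(side - h), 1L), h = h, w = w)
}
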