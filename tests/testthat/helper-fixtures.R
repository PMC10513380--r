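# shared fixtures, built in code at test time

# rasterized disk of radius r (pixels), centered, with margin
mk_disk <- function(r, margin = 6) {
  sz <- ceiling(2 * r) + 2 * margin + 1
  c0 <- (sz + 1) / 2
  matrix(as.numeric(outer((1:sz - c0)^2, (1:sz - c0)^2, "+") <= r^2), sz, sz)
}

# rasterized ball of radius r (voxels)
mk_ball <- function(r, margin = 4) {
  sz <- 2 * r + 2 * margin + 1
  c0 <- r + margin + 1
  g <- expand.grid(x = 1:sz, y = 1:sz, z = 1:sz)
  array(as.numeric((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2),
        c(sz, sz, sz))
}

# brute-force 4-connected component count by flood fill (oracle for
# segmentation label counts on small frames)
flood_fill_count <- function(mask) {
  mask <- mask != 0
  n <- nrow(mask); m <- ncol(mask)
  seen <- matrix(FALSE, n, m)
  count <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > n || p[2] < 1 || p[2] > m) next
      if (!mask[p[1], p[2]] || seen[p[1], p[2]]) next
      seen[p[1], p[2]] <- TRUE
      stack <- c(stack, list(p + c(1, 0), p - c(1, 0),
                             p + c(0, 1), p - c(0, 1)))
    }
  }
  count
}

# match detections to ground truth within a radius (px); returns counts
# for precision/recall (greedy one-to-one matching)
match_detections <- function(det, truth, radius_px) {
  if (nrow(truth) == 0 || nrow(det) == 0)
    return(list(tp = 0, fp = nrow(det), fn = nrow(truth)))
  used <- logical(nrow(truth))
  tp <- 0
  for (i in seq_len(nrow(det))) {
    d2 <- (truth$x_px - det$x_px[i])^2 + (truth$y_px - det$y_px[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] < radius_px^2) { used[j] <- TRUE; tp <- tp + 1 }
  }
  list(tp = tp, fp = nrow(det) - tp, fn = nrow(truth) - tp)
}

f1_score <- function(m) {
  prec <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0
  rec <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
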