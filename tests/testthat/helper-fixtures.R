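# Fixture builders shared across test files. Everything is generated in code.

# filled disk mask (logical) on an n x n grid
disk_mask <- function(n, r, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

# axis-aligned filled ellipse mask
ellipse_mask_fx <- function(n, a_px, b_px, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  ((cols - cx) / a_px)^2 + ((rows - cy) / b_px)^2 <= 1
}

# single-cell phantom for ratio tests: cytoplasm disk, nucleus disk, NE ring
# painted at ne_intensity; returns image + masks (intensity units arbitrary)
cell_phantom <- function(n = 121, r_cell = 50, r_nuc = 22, ring_px = 3,
                         cyto = 50, ne_intensity = 100, nucleoplasm = 30,
                         background = 5, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cell <- disk_mask(n, r_cell)
  nuc <- disk_mask(n, r_nuc)
  ring <- disk_mask(n, r_nuc + ring_px) & !disk_mask(n, r_nuc - ring_px)
  img <- matrix(background, n, n)
  img[cell] <- cyto
  img[nuc] <- nucleoplasm
  img[ring] <- ne_intensity
  if (noise_sd > 0) img <- pmax(img + matrix(rnorm(n * n, 0, noise_sd), n, n), 0)
  list(img = img, cell = cell, nucleus = nuc, ring = ring)
}

# independent flood-fill component count (iterative stack, oracle for
# label_particles)
flood_fill_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  count <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_along(dr)) {
        r <- p[1] + dr[k]; c <- p[2] + dc[k]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  count
}

# brute-force Otsu: between-class variance computed from first principles
# over all 255 split points; plateau ties resolve to the plateau midpoint
otsu_brute <- function(counts) {
  i <- 0:255
  v <- rep(-Inf, 255)
  for (t in 0:254) {
    lo <- counts[i <= t]; hi <- counts[i > t]
    w0 <- sum(lo); w1 <- sum(hi)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:t) * lo) / w0
    mu1 <- sum(((t + 1):255) * hi) / w1
    v[t + 1] <- (w0 / sum(counts)) * (w1 / sum(counts)) * (mu0 - mu1)^2
  }
  ties <- which(v >= max(v) - abs(max(v)) * 1e-10)
  as.integer(floor(mean(range(ties)))) - 1L
}

# brute-force Yen criterion maximizer (splits leaving a class empty are
# ineligible, matching the implementation's convention)
yen_brute <- function(counts) {
  best <- -Inf; best_t <- 0L
  for (t in 0:254) {
    n1 <- sum(counts[1:(t + 1)])
    if (n1 == 0 || n1 == sum(counts)) next
    p <- counts / sum(counts)
    p1 <- sum(p[1:(t + 1)])
    p1sq <- sum(p[1:(t + 1)]^2)
    p2sq <- sum(p^2) - p1sq
    crit <- 0
    if (p1sq * p2sq > 0) crit <- crit - log(p1sq * p2sq)
    if (p1 * (1 - p1) > 0) crit <- crit + 2 * log(p1 * (1 - p1))
    if (crit > best) { best <- crit; best_t <- t }
  }
  best_t
}

# 8-bit histogram of an image, matching the internal binning convention
# (native bins for images already within [0, 255], min-max rescale otherwise)
hist256_fx <- function(image) {
  if (min(image) >= 0 && max(image) <= 255) { lo <- 0; hi <- 255 }
  else { lo <- min(image); hi <- max(image) }
  tabulate(as.integer(round((image - lo) / (hi - lo) * 255)) + 1L, nbins = 256L)
}

# small, fast phantom parameter set for tests that loop over seeds
small_phantom <- function(seed, ...) {
  args <- utils::modifyList(list(field_size_px = c(256L, 256L), n_nuclei = 6L,
                                 n_mn_rich = 2L, n_mn_ne = 2L, seed = seed),
                            list(...))
  do.call(phantom_params, args)
}

# toy nCounter table: one positive control, two negatives, one housekeeping
# gene proportional to the positive control, two endogenous genes
ncounter_toy <- function() {
  m <- rbind(POS1 = c(100, 200, 50),
             NEG1 = c(2, 4, 1),
             NEG2 = c(4, 8, 3),
             HK1  = c(20, 40, 10),
             G1   = c(10, 20, 5),
             G2   = c(3, 50, 2))
  colnames(m) <- c("S1", "S2", "S3")
  m
}

# genes x samples matrix carrying the 9 signature genes plus one extra gene
score_matrix <- function(counts_by_sample) {
  genes <- c(as.character(emd_signature()), "OTHER1")
  m <- do.call(cbind, lapply(counts_by_sample, function(v) c(v, 99)))
  rownames(m) <- genes
  colnames(m) <- sprintf("P%02d", seq_along(counts_by_sample))
  m
}

# brute-force signed MTOC distance: explicit scan over all border pixels
mtoc_brute <- function(nucleus_mask, cy, cx, pixel_size_um) {
  nr <- nrow(nucleus_mask); nc <- ncol(nucleus_mask)
  best <- Inf
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!nucleus_mask[r, c]) next
    nb_out <- (r == 1 || !nucleus_mask[r - 1, c]) ||
      (r == nr || !nucleus_mask[r + 1, c]) ||
      (c == 1 || !nucleus_mask[r, c - 1]) ||
      (c == nc || !nucleus_mask[r, c + 1])
    if (nb_out) best <- min(best, sqrt((r - cy)^2 + (c - cx)^2))
  }
  sgn <- if (nucleus_mask[round(cy), round(cx)]) -1 else 1
  sgn * best * pixel_size_um
}
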