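# Shared fixtures: exact disc rasterisation, brute-force oracles, and small
# scene builders. Everything is generated in code under fixed seeds.

# Rasterise discs (id, x_um, y_um, r_um) as a binary 8-bit image by the
# pixel-center rule; value 200 on a 0 background.
draw_discs <- function(discs, window, pixel_size_um, value = 200) {
  nx <- round(window[1] / pixel_size_um)
  ny <- round(window[2] / pixel_size_um)
  img <- matrix(0, ny, nx)
  xs <- (seq_len(nx) - 0.5) * pixel_size_um
  ys <- (seq_len(ny) - 0.5) * pixel_size_um
  for (i in seq_len(nrow(discs))) {
    cols <- which(abs(xs - discs$x_um[i]) <= discs$r_um[i] + pixel_size_um)
    rows <- which(abs(ys - discs$y_um[i]) <= discs$r_um[i] + pixel_size_um)
    if (!length(cols) || !length(rows)) next
    hit <- outer((ys[rows] - discs$y_um[i])^2, (xs[cols] - discs$x_um[i])^2,
                 "+") <= discs$r_um[i]^2
    img[rows, cols][hit] <- value
  }
  img
}

# Random non-overlapping discs: rejection sampling with a minimum
# boundary-to-boundary separation `min_gap` (> 0 keeps objects distinct).
random_disc_scene <- function(n, window, r_range = c(4, 8), min_gap = 1,
                              margin = 15) {
  xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
  tries <- 0
  while (length(xs) < n && tries < 20000) {
    tries <- tries + 1
    x <- runif(1, margin, window[1] - margin)
    y <- runif(1, margin, window[2] - margin)
    r <- runif(1, r_range[1], r_range[2])
    if (length(xs) == 0 ||
        all(sqrt((xs - x)^2 + (ys - y)^2) > rs + r + min_gap)) {
      xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
    }
  }
  data.frame(id = seq_along(xs), x_um = xs, y_um = ys, r_um = rs)
}

# O(n^2) all-pairs NND, plain and toroidal.
brute_nnd <- function(x, y, window = NULL, toroidal = FALSE) {
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  if (toroidal) {
    dx <- pmin(dx, window[1] - dx)
    dy <- pmin(dy, window[2] - dy)
  }
  d <- sqrt(dx^2 + dy^2)
  diag(d) <- Inf
  apply(d, 1, min)
}

# Points placed on a jittered grid: guaranteed pairwise separation, used for
# detection round-trips where objects must stay isolated.
separated_points <- function(n, window, spacing, jitter = 0.2 * spacing) {
  ncol_g <- ceiling(sqrt(n))
  centers <- expand.grid(
    x = seq(spacing / 2, window[1] - spacing / 2, by = spacing),
    y = seq(spacing / 2, window[2] - spacing / 2, by = spacing))
  stopifnot(nrow(centers) >= n)
  centers <- centers[seq_len(n), ]
  tibble::tibble(
    x_um = centers$x + runif(n, -jitter, jitter),
    y_um = centers$y + runif(n, -jitter, jitter))
}

# Exhaustive one-to-one matching oracle for colocalization on small
# instances: maximises the number of pairs within `max_d`, breaking ties by
# smaller total distance. Returns the optimal pair count and total distance.
coloc_oracle <- function(a, b, max_d) {
  na <- nrow(a); nb <- nrow(b)
  d <- sqrt(outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2)
  best <- list(n = 0, total = Inf)
  recurse <- function(i, used_b, n_pairs, total) {
    if (i > na) {
      if (n_pairs > best$n ||
          (n_pairs == best$n && total < best$total)) {
        best <<- list(n = n_pairs, total = total)
      }
      return(invisible())
    }
    # bound: even pairing every remaining a cannot beat best
    if (n_pairs + (na - i + 1) < best$n) return(invisible())
    for (j in seq_len(nb)) {
      if (!used_b[j] && d[i, j] <= max_d) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, n_pairs + 1, total + d[i, j])
        used_b[j] <- FALSE
      }
    }
    recurse(i + 1, used_b, n_pairs, total)
  }
  recurse(1, logical(nb), 0, 0)
  best
}

# Map segmented objects back to the generating discs/points by nearest
# centroid (only meaningful when counts match or separations are large).
match_to_truth <- function(objects, truth) {
  vapply(seq_len(nrow(objects)), function(k) {
    which.min((truth$x_um - objects$x_um[k])^2 +
                (truth$y_um - objects$y_um[k])^2)
  }, integer(1))
}

# Partition-equality check between detector membership and oracle labels:
# same clustered object set and identical grouping structure.
same_partition <- function(ids_a, ids_b) {
  if (!identical(is.na(ids_a), is.na(ids_b))) return(FALSE)
  ok <- !is.na(ids_a)
  if (!any(ok)) return(TRUE)
  ta <- as.integer(factor(ids_a[ok], levels = unique(ids_a[ok])))
  tb <- as.integer(factor(ids_b[ok], levels = unique(ids_b[ok])))
  identical(ta, tb)
}
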