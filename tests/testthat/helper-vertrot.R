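# shared helpers: independent oracles and small utilities

# circular distance between axial angles (mod 180)
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# independent shoelace area
shoelace <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Exhaustive per-pixel reflection oracle for the mirror-overlap symmetry
# ratio, written directly from the definition: reflect every foreground
# pixel centre across the axis through the centroid and accumulate the
# bilinearly weighted foreground coverage at the mirrored position.
# Independent R implementation of the same continuous-reflection definition
# used by the compiled kernel.
oracle_symmetry_ratio <- function(mask, angle_deg) {
  idx <- which(mask, arr.ind = TRUE)
  py <- idx[, 1]
  px <- idx[, 2]
  cx <- mean(px)
  cy <- mean(py)
  th <- angle_deg * pi / 180
  ux <- sin(th)
  uy <- cos(th)
  m <- 1 * mask
  nr <- nrow(mask)
  nc <- ncol(mask)
  getpix <- function(x, y) {
    ok <- x >= 1 & x <= nc & y >= 1 & y <= nr
    v <- numeric(length(x))
    v[ok] <- m[cbind(y[ok], x[ok])]
    v
  }
  dx <- px - cx
  dy <- py - cy
  pr <- dx * ux + dy * uy
  qx <- cx + 2 * pr * ux - dx
  qy <- cy + 2 * pr * uy - dy
  x0 <- floor(qx)
  y0 <- floor(qy)
  fx <- qx - x0
  fy <- qy - y0
  val <- getpix(x0, y0) * (1 - fx) * (1 - fy) +
    getpix(x0 + 1, y0) * fx * (1 - fy) +
    getpix(x0, y0 + 1) * (1 - fx) * fy +
    getpix(x0 + 1, y0 + 1) * fx * fy
  sum(val) / length(px)
}

# tiny synthetic cohort builder
make_cohort <- function(n, injected_fun = function(i) numeric(),
                        seed_offset = 0) {
  lapply(seq_len(n), function(i) {
    generate_spine_study(
      spine_study_spec(patient = sprintf("P%02d", i),
                       injected_changes = injected_fun(i),
                       seed = i + seed_offset),
      outlines = FALSE)
  })
}
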