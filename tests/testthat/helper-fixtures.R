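# shared fixtures and independent oracles

# one small valid drug plate: 3 WT, 3 MT, 2 FCCP, a few treatments
make_drug_plate <- function(plate_id = "P01_A", wt = c(0.40, 0.50, 0.60),
                            mt = c(0.30, 0.32, 0.34), fccp = c(0.05, 0.06),
                            treatments = c(T0001 = 0.35, T0002 = 0.45)) {
  ratios <- c(wt, mt, fccp, unname(treatments))
  roles <- c(rep("wt_control", length(wt)), rep("mt_control", length(mt)),
             rep("fccp_control", length(fccp)),
             rep("treatment", length(treatments)))
  ids <- c(rep(NA_character_, length(wt) + length(mt) + length(fccp)),
           names(treatments))
  f520 <- rep(1000, length(ratios))
  tibble::tibble(
    plate_id = plate_id,
    well = c("A12", "B12", "C12", "D12", "E12", "F12", "G12", "H12",
             paste0(LETTERS[seq_along(treatments)], 1))[seq_along(ratios)],
    role = roles, treatment_id = ids,
    f590 = ratios * f520, f520 = f520
  )
}

# rasterized shapes on pixel grids
disc_mask <- function(r, size = 2 * r + 24) {
  m <- matrix(FALSE, size, size)
  ctr <- (size + 1) / 2
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= r^2] <- TRUE
  m
}

ellipse_mask <- function(a, b, size = 2 * ceiling(a) + 24, theta = 0) {
  m <- matrix(FALSE, size, size)
  ctr <- (size + 1) / 2
  dx <- col(m) - ctr
  dy <- row(m) - ctr
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  m[(u / a)^2 + (v / b)^2 <= 1] <- TRUE
  m
}

rect_mask <- function(h, w, size = max(h, w) + 24) {
  m <- matrix(FALSE, size, size)
  r0 <- floor((size - h) / 2)
  c0 <- floor((size - w) / 2)
  m[r0 + seq_len(h), c0 + seq_len(w)] <- TRUE
  m
}

sd_mle_oracle <- function(x) sqrt(mean((x - mean(x))^2))

# independent closed-form Gaussian MLE (the k = 1 oracle)
oracle_normal_mle <- function(x) {
  mu <- sum(x) / length(x)
  list(mean = mu, sd = sqrt(sum((x - mu)^2) / length(x)),
       loglik = sum(dnorm(x, mu, sqrt(sum((x - mu)^2) / length(x)),
                          log = TRUE)))
}

# straight chain along +x: soma at origin plus `n_seg` segments
chain_tree <- function(n_seg = 2, seg = 50) {
  n <- n_seg + 1
  neuron_tree(tibble::tibble(
    id = seq_len(n), type = c(1L, rep(3L, n - 1)),
    x = (seq_len(n) - 1) * seg, y = 0, z = 0, radius = 1,
    parent = c(-1L, seq_len(n - 1))
  ))
}

# trunk of 50 um up the y axis, then two 40 um branches spreading outward
y_tree <- function() {
  b <- 40 / sqrt(2)
  neuron_tree(tibble::tibble(
    id = 1:4, type = c(1L, 3L, 3L, 3L),
    x = c(0, 0, b, -b), y = c(0, 50, 50 + b, 50 + b), z = 0, radius = 1,
    parent = c(-1L, 1L, 2L, 2L)
  ))
}

full_binary_tree <- function(depth, seg = 10) {
  nodes <- tibble::tibble(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                          radius = 1, parent = -1L)
  frontier <- tibble::tibble(id = 1L, x = 0, y = 0)
  next_id <- 2L
  for (d in seq_len(depth)) {
    new_frontier <- NULL
    for (i in seq_len(nrow(frontier))) {
      for (s in c(-1, 1)) {
        nodes <- dplyr::bind_rows(nodes, tibble::tibble(
          id = next_id, type = 3L,
          x = frontier$x[i] + s * seg / sqrt(2),
          y = frontier$y[i] + seg / sqrt(2), z = 0, radius = 1,
          parent = frontier$id[i]
        ))
        new_frontier <- dplyr::bind_rows(
          new_frontier,
          tibble::tibble(id = next_id, x = frontier$x[i] + s * seg / sqrt(2),
                         y = frontier$y[i] + seg / sqrt(2)))
        next_id <- next_id + 1L
      }
    }
    frontier <- new_frontier
  }
  neuron_tree(nodes)
}
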