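# Shared fixture builders: everything is generated in code at test time.

# small grid with a unit transform anchored at the origin
mk_grid <- function(values, dx = 1, dy = 1, mask = NULL) {
  values <- as.matrix(values)
  new_grid(values,
           list(x0 = 0, y0 = (nrow(values) - 1) * dy, dx = dx, dy = dy),
           mask = mask)
}

# annual stack from a pixels-in-rows matrix (nr x nc x years)
mk_annual_stack <- function(arr, years) {
  grid_stack(arr, years = years,
             transform = list(x0 = 0, y0 = (dim(arr)[1] - 1) * 1, dx = 1, dy = 1))
}

# brute-force oracles, independent of the package implementations -----------

oracle_theil_sen <- function(x, t = seq_along(x)) {
  sl <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    sl <- c(sl, (x[j] - x[i]) / (t[j] - t[i]))
  sort(sl)[c(ceiling(length(sl) / 2), floor(length(sl) / 2) + 1)] |>
    mean()
}

oracle_mk_s <- function(x) {
  s <- 0L
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i])
  s
}

# exhaustive Fisher-Jenks: all contiguous partitions of the sorted sample
oracle_jenks_objective <- function(v, k) {
  v <- sort(v)
  n <- length(v)
  ssd <- function(z) sum((z - mean(z))^2)
  best <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  for (c_ in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, c_], n)
    obj <- sum(vapply(seq_len(k), function(g) ssd(v[(b[g] + 1):b[g + 1]]),
                      numeric(1)))
    if (obj < best) best <- obj
  }
  best
}

# geodetector q from the definition (stratum-variance form of the statistic)
oracle_q <- function(y, h) {
  N <- length(y)
  sigma2 <- mean((y - mean(y))^2)
  strata <- split(y, h)
  1 - sum(vapply(strata, function(v) length(v) * mean((v - mean(v))^2),
                 numeric(1))) / (N * sigma2)
}

# total effects by explicit path enumeration over a DAG
oracle_total_effects <- function(P) {
  lat <- rownames(P)
  J <- length(lat)
  total <- matrix(0, J, J, dimnames = dimnames(P))
  walk <- function(node, target, prod) {
    if (node == target) return(prod)
    out <- 0
    for (nxt in which(P[node, ] != 0))
      out <- out + walk(nxt, target, prod * P[node, nxt])
    out
  }
  for (s in seq_len(J)) for (t in seq_len(J)) if (s != t) {
    for (nxt in which(P[s, ] != 0))
      total[s, t] <- total[s, t] + walk(nxt, t, P[s, nxt])
  }
  total
}
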