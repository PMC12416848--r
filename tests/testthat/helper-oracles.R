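# Independent oracles: scalar loop transcriptions and brute-force references.
# These deliberately avoid the package's vectorized/compiled code paths.

# term-by-term scalar transcription of the growth equations
scalar_rhs <- function(x, net, traits, params) {
  S <- length(x)
  out <- numeric(S)
  for (i in seq_len(S)) {
    npos <- 0
    for (j in seq_len(S)) {
      if (net$m[i, j] > 0) npos <- npos + 1
      if (net$pplus[i, j] > 0) npos <- npos + 1
    }
    denom_ip <- 1
    denom_im <- 1
    for (k in seq_len(S)) {
      denom_ip <- denom_ip + params$h_p * net$pplus[i, k] * x[k]
      denom_im <- denom_im + params$h_m * net$m[i, k] * x[k]
    }
    neg <- traits$r[i] - params$delta * npos - traits$s[i] * x[i]
    for (j in seq_len(S)) {
      denom_j <- 1
      for (k in seq_len(S))
        denom_j <- denom_j + params$h_p * net$pplus[j, k] * x[k]
      neg <- neg - net$c[i, j] * x[j] - net$pminus[i, j] * x[j] / denom_j
    }
    pos <- 0
    for (j in seq_len(S))
      pos <- pos + net$pplus[i, j] * x[j] / denom_ip +
        net$m[i, j] * x[j] / denom_im
    out[i] <- x[i] * neg + x[i] * pos
  }
  out
}

# random valid community: each unordered pair carries at most one type
random_community <- function(S, p_link = 0.4, sigma = 0.2) {
  cmat <- matrix(0, S, S); pp <- matrix(0, S, S)
  pm <- matrix(0, S, S); mm <- matrix(0, S, S)
  if (S >= 2) {
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      if (runif(1) >= p_link) next
      type <- sample(c("comp", "cons", "mut"), 1)
      w <- abs(rnorm(2, 0, sigma))
      if (type == "comp") {
        cmat[i, j] <- w[1]; cmat[j, i] <- w[2]
      } else if (type == "mut") {
        mm[i, j] <- w[1]; mm[j, i] <- w[2]
      } else if (runif(1) < 0.5) {
        pp[i, j] <- min(w[1], w[2]); pm[j, i] <- w[2]
      } else {
        pp[j, i] <- min(w[1], w[2]); pm[i, j] <- w[2]
      }
    }
  }
  community(x = runif(S, 0.01, 1),
            r = rnorm(S, 0.1, 0.01), s = 1 / rlnorm(S, 0.1, 0.5),
            c = cmat, pplus = pp, pminus = pm, m = mm)
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
set_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxblock) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxblock + 1))
      grow(c(prefix, b), max(maxblock, b))
  }
  grow(integer(0), 0L)
  out
}

# direct evaluation of the partition-quality score
modularity_formula <- function(graph, membership, resolution = 1) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  m <- nrow(el)
  deg <- igraph::degree(graph)
  total <- 0
  for (b in unique(membership)) {
    nodes <- which(membership == b)
    L_c <- sum(el[, 1] %in% nodes & el[, 2] %in% nodes)
    k_c <- sum(deg[nodes])
    total <- total + L_c / m - resolution * (k_c / (2 * m))^2
  }
  total
}

# brute-force maximum modularity over every partition (feasible for n <= 8)
exhaustive_modularity <- function(graph, resolution = 1) {
  parts <- set_partitions(igraph::vcount(graph))
  max(vapply(parts, function(p) modularity_formula(graph, p, resolution),
             numeric(1)))
}

# central finite differences of the scalar-oracle RHS (independent of
# jacobian_at and of growth_rhs)
oracle_jacobian_fd <- function(community, params) {
  x <- community$x
  S <- length(x)
  J <- matrix(0, S, S)
  for (j in seq_len(S)) {
    h <- max(1e-7, 1e-4 * x[j])
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- max(x[j] - h, 0)
    J[, j] <- (scalar_rhs(xp, community$net, community$traits, params) -
                 scalar_rhs(xm, community$net, community$traits, params)) /
      (xp[j] - xm[j])
  }
  J
}

# standard small fixtures
fixture_two_mutualists <- function(w12 = 0.2, w21 = 0.2, x0 = 0.1) {
  make_community(
    data.frame(id = c("a", "b"), r = 0.1, s = 1, x0 = x0),
    data.frame(from = "a", to = "b", type = "mutualism",
               w_ft = w12, w_tf = w21))
}

fixture_three_chain <- function() {
  # c consumes b consumes a
  make_community(
    data.frame(id = c("a", "b", "c"), r = c(0.1, 0.05, 0.02), s = 1,
               x0 = c(0.3, 0.1, 0.05)),
    data.frame(from = c("b", "c"), to = c("a", "b"),
               type = "consumer_resource",
               w_ft = c(0.15, 0.1), w_tf = c(0.2, 0.12)))
}
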