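# Independent oracles used across the suite.

# Fieller set by brute numerical solution: the quadratic inequality is
# evaluated on a fine grid to locate sign changes, each refined by uniroot.
# Returns list(type, lo, hi): type "interval", "exclusive", "line".
fiellerGridOracle <- function(b1, b2, v11, v22, v12, df, level = 0.95) {
  tc <- qt(1 - (1 - level) / 2, df)
  g <- function(rho) (b2^2 - tc^2 * v22) * rho^2 -
    2 * (b1 * b2 - tc^2 * v12) * rho + (b1^2 - tc^2 * v11)
  center <- b1 / b2
  span <- 1000 * (abs(center) + sqrt(v11 + v22) / max(abs(b2), 1e-12) + 1)
  grid <- center + span * seq(-1, 1, length.out = 400001)
  s <- g(grid)
  flips <- which(diff(sign(s)) != 0)
  roots <- vapply(flips, function(i)
    uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-12)$root, numeric(1))
  inside <- s <= 0
  if (length(roots) == 2) {
    if (g(mean(roots)) <= 0) list(type = "interval", lo = roots[1],
                                  hi = roots[2])
    else list(type = "exclusive", lo = roots[1], hi = roots[2])
  } else if (length(roots) == 0) {
    list(type = if (all(inside)) "line" else "empty", lo = -Inf, hi = Inf)
  } else list(type = "half", lo = roots, hi = NA)
}

# Maximum bipartite matching size via igraph, on an explicit compatibility
# graph between cases and controls.
maxMatchingOracle <- function(cases, controls, compatible) {
  nc <- nrow(cases); nh <- nrow(controls)
  edges <- c()
  for (i in seq_len(nc)) for (j in seq_len(nh))
    if (compatible(cases[i, ], controls[j, ]))
      edges <- c(edges, i, nc + j)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nc), rep(TRUE, nh)),
                                    edges = edges)
  igraph::max_bipartite_match(g)$matching_size
}

# Hand step-up BH for cross-checking
bhByHand <- function(p) {
  m <- length(p)
  o <- order(p)
  raw <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(raw, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# small deterministic cohort for filter/matching unit tests
tinyCohort <- function() {
  data.frame(
    id = sprintf("P%02d", 1:8),
    age = c(63, 63, 64, 70, 70, 70, 55, 55),
    sex = c("female", "female", "male", "male", "male", "male", "female",
            "female"),
    education = rep("degree", 8),
    sbp = c(120, 150, 140, 120, 141, 120, 120, 120),
    dbp = c(80, 80, 90, 95, 80, 80, 80, 80),
    menopause = c(TRUE, TRUE, NA, NA, NA, NA, TRUE, FALSE),
    hormone_therapy = c(FALSE, FALSE, NA, NA, NA, NA, TRUE, FALSE),
    t2dm = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    onset_report_1 = c(45, NA, 38, NA, 60, NA, 50, NA),
    onset_report_2 = c(47, NA, 38, NA, 61, NA, NA, NA),
    onset_report_3 = c(49, NA, 38, NA, 59, NA, NA, NA),
    metformin = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    other_t2dm_medication = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                              FALSE, FALSE),
    bmi = rep(27, 8),
    head_scaling = rep(1, 8),
    stringsAsFactors = FALSE)
}
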