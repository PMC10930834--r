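# Independent oracles for the envelopment solver.

# CRS input-oriented efficiency by exhaustive vertex enumeration of the
# multiplier polytope {u, v >= 0 : v'x_o = 1, u'y_k - v'x_k <= 0}: every
# basic feasible point is the unique solution of the equality row plus p-1
# active constraints; the optimum is the best vertex. Exponential in the
# variable count, usable only for tiny instances -- which is the point.
crs_input_oracle <- function(X, Y, o) {
  m <- ncol(Y); p <- ncol(X) + m
  A <- rbind(cbind(Y, -X), -diag(p))   # rows g with g'z <= 0, z = (u, v)
  eq <- c(numeric(m), X[o, ])
  best <- -Inf
  for (S in utils::combn(nrow(A), p - 1, simplify = FALSE)) {
    M <- rbind(eq, A[S, , drop = FALSE])
    z <- tryCatch(solve(M, c(1, numeric(p - 1))), error = function(e) NULL)
    if (is.null(z)) next
    if (all(A %*% z <= 1e-9)) best <- max(best, sum(z[seq_len(m)] * Y[o, ]))
  }
  best
}

# random small DMU table for property-style loops
random_table <- function(H, n_inputs = 2, seed) {
  withr::with_seed(seed, {
    d <- data.frame(dmu = seq_len(H),
                    matrix(runif(H * n_inputs, 1, 10), H),
                    y = runif(H, 1, 10))
    names(d) <- c("dmu", paste0("x", seq_len(n_inputs)), "y")
    dmu_table(d, input_names = paste0("x", seq_len(n_inputs)),
              output_names = "y")
  })
}
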