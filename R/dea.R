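#' Specify a DEA model
#'
#' Chooses the returns-to-scale assumption, the orientation, the frontier
#' side, and the treatment of the non-Archimedean epsilon.
#'
#' @param rts returns to scale: `"crs"` (the CCR model, constant returns)
#'   or `"vrs"` (the BCC model, variable returns: the envelopment adds the
#'   convexity constraint sum(lambda) = 1; the multiplier form gains a
#'   sign-free scale variable).
#' @param orientation `"input"` (contract inputs at given outputs) or
#'   `"output"` (expand outputs at given inputs). Output-oriented scores
#'   are reported as 1/phi so every published score lives in (0, 1].
#' @param frontier `"standard"` or `"inverted"`; the inverted frontier swaps
#'   input and output roles (see [invert_dmu_table()]) and scores proximity
#'   to worst practice.
#' @param epsilon `"two_phase"` (default) realises the infinitesimal weight
#'   bound by a second LP phase that maximises total slack at the fixed
#'   optimal radial factor -- radial scores are then exactly
#'   epsilon-independent. `"explicit"` instead adds the lower bound
#'   `eps_value` to all multiplier weights, mimicking classical solver
#'   configurations; it perturbs scores at roughly the size of eps_value.
#' @param eps_value explicit epsilon; positive and at most 1e-4.
#' @return an object of class `dea_model`.
#' @export
dea_model <- function(rts = c("crs", "vrs"),
                      orientation = c("input", "output"),
                      frontier = c("standard", "inverted"),
                      epsilon = c("two_phase", "explicit"),
                      eps_value = 1e-6) {
  rts <- match.arg(rts)
  orientation <- match.arg(orientation)
  frontier <- match.arg(frontier)
  epsilon <- match.arg(epsilon)
  if (epsilon == "explicit" &&
      (!is.numeric(eps_value) || eps_value <= 0 || eps_value > 1e-4))
    stop("explicit epsilon must lie in (0, 1e-4]", call. = FALSE)
  structure(list(rts = rts, orientation = orientation, frontier = frontier,
                 epsilon = epsilon, eps_value = eps_value),
            class = "dea_model")
}

#' @export
print.dea_model <- function(x, ...) {
  cat(sprintf("DEA model: %s, %s-oriented, %s frontier, epsilon = %s\n",
              toupper(x$rts), x$orientation, x$frontier,
              if (x$epsilon == "two_phase") "two-phase"
              else format(x$eps_value)))
  invisible(x)
}

# ---- LP layer -------------------------------------------------------------
# Dense two-phase primal simplex with Bland's anti-cycling rule. DEA
# envelopment problems are small (tens of variables and rows) but routinely
# degenerate at efficient units, which trips the simplex implementations
# available here; this engine pivots artificial variables out explicitly and
# drops redundant rows, so degenerate optima are handled exactly. Columns
# are mean-scaled before assembly (housing ~ 1e6 against cost ~ 4 would
# otherwise put six orders of magnitude into one basis), keeping entries
# near 1 so an absolute pivot tolerance is meaningful.

# min cvec'x  s.t.  A x (dir) b, x >= 0;  dir in {-1 (<=), 0 (=), 1 (>=)}
simplex_core <- function(cvec, A, dir, b, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
    dir[flip] <- -dir[flip]
  }
  n_slack <- sum(dir == -1); n_surp <- sum(dir == 1); n_art <- sum(dir != -1)
  N <- n + n_slack + n_surp + n_art
  Tab <- matrix(0, m, N + 1)
  Tab[, seq_len(n)] <- A
  Tab[, N + 1] <- b
  basis <- integer(m)
  js <- n; ja <- n + n_slack + n_surp
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (dir[i] == -1) {
      js <- js + 1L; Tab[i, js] <- 1; basis[i] <- js
    } else {
      if (dir[i] == 1) { js_s <- n + n_slack + sum(dir[seq_len(i)] == 1)
        Tab[i, js_s] <- -1 }
      ja <- ja + 1L; Tab[i, ja] <- 1; basis[i] <- ja
      art_cols <- c(art_cols, ja)
    }
  }

  pivot <- function(r, j) {
    Tab[r, ] <<- Tab[r, ] / Tab[r, j]
    for (i in seq_len(nrow(Tab))) if (i != r && abs(Tab[i, j]) > 0)
      Tab[i, ] <<- Tab[i, ] - Tab[i, j] * Tab[r, ]
    basis[r] <<- j
  }
  iterate <- function(cost, allowed) {
    for (it in seq_len(max_iter)) {
      cb <- cost[basis]
      red <- cost[seq_len(N)] -
        as.vector(crossprod(Tab[, seq_len(N), drop = FALSE], cb))
      cand <- which(allowed & red < -tol)
      if (!length(cand)) return(TRUE)
      j <- cand[1L]                                  # Bland: smallest index
      pos <- which(Tab[, j] > tol)
      if (!length(pos)) return(NA)                   # unbounded
      ratio <- Tab[pos, N + 1] / Tab[pos, j]
      r <- pos[ratio <= min(ratio) + 1e-10]
      r <- r[which.min(basis[r])]                    # Bland tie-break
      pivot(r, j)
    }
    stop("simplex iteration limit reached", call. = FALSE)
  }

  allowed <- rep(TRUE, N)
  if (n_art > 0) {
    cost1 <- numeric(N); cost1[art_cols] <- 1
    ok <- iterate(cost1, allowed)
    obj1 <- sum(Tab[basis %in% art_cols, N + 1])
    if (is.na(ok) || obj1 > 1e-7)
      return(list(status = 2L, value = NA_real_, x = NULL))  # infeasible
    allowed[art_cols] <- FALSE
    # pivot remaining (degenerate) artificials out, or drop redundant rows
    drop_rows <- integer(0)
    for (r in which(basis %in% art_cols)) {
      j <- which(allowed & abs(Tab[r, seq_len(N)]) > tol)[1]
      if (is.na(j)) drop_rows <- c(drop_rows, r) else pivot(r, j)
    }
    if (length(drop_rows)) {
      Tab <- Tab[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
    }
  }
  cost2 <- numeric(N); cost2[seq_len(n)] <- cvec
  ok <- iterate(cost2, allowed)
  if (is.na(ok)) return(list(status = 3L, value = NA_real_, x = NULL))
  x <- numeric(N)
  x[basis] <- Tab[, N + 1]
  list(status = 0L, value = sum(cvec * x[seq_len(n)]), x = x[seq_len(n)])
}

# boot::simplex-style interface: max/min a'x s.t. A1 x <= b1, A2 x >= b2,
# A3 x = b3, x >= 0.
lp_solve <- function(a, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                     A3 = NULL, b3 = NULL, maxi = FALSE) {
  A <- rbind(A1, A2, A3)
  dir <- c(rep(-1L, NROW(A1)), rep(1L, NROW(A2)), rep(0L, NROW(A3)))
  b <- c(b1, b2, b3)
  s <- simplex_core(if (maxi) -a else a, A, dir, b)
  if (s$status != 0L)
    stop("LP not solved (status ", s$status, ")", call. = FALSE)
  list(value = if (maxi) -s$value else s$value, x = s$x)
}

# Radial envelopment LP for one DMU (phase 1).
# input orientation:  min theta : sum(lambda x) <= theta x_o, sum(lambda y) >= y_o
# output orientation: max phi   : sum(lambda x) <= x_o, sum(lambda y) >= phi y_o
# vrs adds sum(lambda) = 1.
envelope_radial <- function(X, Y, o, rts, orientation) {
  H <- nrow(X); n <- ncol(X); m <- ncol(Y)
  if (orientation == "input") {
    a <- c(1, numeric(H))
    A1 <- cbind(-X[o, ], t(X))          # sum(lambda x_j) - theta x_jo <= 0
    b1 <- numeric(n)
    A2 <- cbind(numeric(m), t(Y))       # sum(lambda y_i) >= y_io
    b2 <- Y[o, ]
    maxi <- FALSE
  } else {
    a <- c(1, numeric(H))
    A1 <- cbind(numeric(n), t(X))       # sum(lambda x_j) <= x_jo
    b1 <- X[o, ]
    A2 <- cbind(-Y[o, ], t(Y))          # sum(lambda y_i) - phi y_io >= 0
    b2 <- numeric(m)
    maxi <- TRUE
  }
  if (rts == "vrs") {
    A3 <- matrix(c(0, rep(1, H)), 1)
    s <- lp_solve(a, A1, b1, A2, b2, A3, 1, maxi = maxi)
  } else {
    s <- lp_solve(a, A1, b1, A2, b2, maxi = maxi)
  }
  list(radial = s$value, lambda = s$x[seq_len(H) + 1])
}

# Phase 2: at the fixed radial factor, maximise the slack sum.
# input orientation:  sum(lambda x) + s- <= theta* x_o ; sum(lambda y) - s+ >= y_o
# output orientation: sum(lambda x) + s- <= x_o        ; sum(lambda y) - s+ >= phi* y_o
# Maximising the slack sum drives both row sets to bind, so the optimum
# coincides with the equality formulation while tolerating the radial
# factor's floating-point error.
envelope_slacks <- function(X, Y, o, rts, orientation, radial) {
  H <- nrow(X); n <- ncol(X); m <- ncol(Y)
  xt <- if (orientation == "input") radial * X[o, ] else X[o, ]
  yt <- if (orientation == "input") Y[o, ] else radial * Y[o, ]
  # variables: lambda (H), s- (n), s+ (m)
  a <- c(numeric(H), rep(1, n + m))
  A1 <- cbind(t(X), diag(n), matrix(0, n, m))
  A2 <- cbind(t(Y), matrix(0, m, n), -diag(m))
  if (rts == "vrs") {
    A3 <- matrix(c(rep(1, H), numeric(n + m)), 1)
    s <- lp_solve(a, A1 = A1, b1 = xt, A2 = A2, b2 = yt, A3 = A3, b3 = 1,
                  maxi = TRUE)
  } else {
    s <- lp_solve(a, A1 = A1, b1 = xt, A2 = A2, b2 = yt, maxi = TRUE)
  }
  list(lambda = s$x[seq_len(H)],
       slack_in = s$x[H + seq_len(n)],
       slack_out = s$x[H + n + seq_len(m)])
}

# Multiplier (primal ratio-form linearisation) LP: virtual weights.
# input orientation, CRS:  max u'y_o : v'x_o = 1, u'y_k - v'x_k <= 0, u, v >= eps
# VRS adds a sign-free scale term, handled as the difference of two
# nonnegative variables. Output orientation minimises v'x_o with u'y_o = 1.
multiplier_weights <- function(X, Y, o, rts, orientation, eps = 0) {
  H <- nrow(X); n <- ncol(X); m <- ncol(Y)
  nfree <- if (rts == "vrs") 2L else 0L        # w = w+ - w-
  nv <- m + n + nfree
  sgn <- if (orientation == "input") 1 else -1
  wcol <- if (rts == "vrs") cbind(rep(sgn, H), rep(-sgn, H)) else NULL
  # ratio constraints: u'y_k - v'x_k (+ w) <= 0   (input orientation)
  #                    v'x_k - u'y_k (- w) >= 0 is the same row set
  A1 <- cbind(Y, -X, wcol)
  b1 <- numeric(H)
  if (orientation == "input") {
    a <- c(Y[o, ], numeric(n), if (nfree) c(1, -1))
    A3 <- matrix(c(numeric(m), X[o, ], numeric(nfree)), 1)
    maxi <- TRUE
  } else {
    a <- c(numeric(m), X[o, ], if (nfree) c(1, -1))
    A3 <- matrix(c(Y[o, ], numeric(n), numeric(nfree)), 1)
    maxi <- FALSE
  }
  if (eps > 0) {
    # mu_i, v_j >= eps via substitution would change A3; bound directly
    A2 <- cbind(diag(m + n), matrix(0, m + n, nfree))
    s <- lp_solve(a, A1 = A1, b1 = b1, A2 = A2, b2 = rep(eps, m + n),
                  A3 = A3, b3 = 1, maxi = maxi)
  } else {
    s <- lp_solve(a, A1 = A1, b1 = b1, A3 = A3, b3 = 1, maxi = maxi)
  }
  w <- if (nfree) s$x[m + n + 1] - s$x[m + n + 2] else NULL
  list(value = s$value, mu = s$x[seq_len(m)], v = s$x[m + seq_len(n)],
       u_free = w)
}

# ---- user-facing solves ---------------------------------------------------

#' Solve a DEA model for every DMU
#'
#' Runs the envelopment LP for each unit: phase 1 finds the optimal radial
#' factor, phase 2 maximises total slack at that factor (the two-phase
#' realisation of the non-Archimedean epsilon), and a multiplier-form LP
#' recovers virtual weights. Columns are mean-scaled internally for
#' numerical conditioning; radial scores are invariant to any positive
#' column scaling.
#'
#' @param table a [dmu_table()].
#' @param model a [dea_model()]; default CCR (constant returns),
#'   input-oriented, standard frontier.
#' @param ids DMU ids to solve (default: all).
#' @return an object of class `dea_result`: a list with
#' \describe{
#'   \item{scores}{named vector in (0, 1]; output orientation reports 1/phi}
#'   \item{radial}{the raw radial factor (theta, or phi >= 1)}
#'   \item{lambda}{peer intensity matrix (rows: evaluated DMU; columns: peers)}
#'   \item{slack_in, slack_out}{input / output slacks after the radial move}
#'   \item{targets}{projected frontier point per DMU (inputs then outputs)}
#'   \item{benchmarks}{list of peer id vectors (lambda > 1e-6)}
#'   \item{weights}{multiplier weights mu, v (and the VRS scale term);
#'     alternate optima exist, so weights are reported, not unique}
#' }
#' @export
#' @examples
#' res <- dea(broiler_batches(), dea_model("crs", "input"))
#' head(round(res$scores, 6))
#' efficient_dmus(res)
dea <- function(table, model = dea_model(), ids = NULL) {
  stopifnot(is.dmu_table(table), inherits(model, "dea_model"))
  if (model$frontier == "inverted") table <- invert_dmu_table(table)
  X <- input_matrix(table); Y <- output_matrix(table)
  # mean-scale for conditioning (scores invariant)
  X <- sweep(X, 2, colMeans(X), "/")
  Y <- sweep(Y, 2, colMeans(Y), "/")
  all_ids <- table$dmu
  if (is.null(ids)) ids <- all_ids
  rows <- match(ids, all_ids)
  if (anyNA(rows))
    stop("unknown DMU id(s): ", paste(ids[is.na(rows)], collapse = ", "),
         call. = FALSE)
  H <- nrow(X); n <- ncol(X); m <- ncol(Y)
  eps <- if (model$epsilon == "explicit") model$eps_value else 0

  radial <- numeric(length(rows))
  lambda <- matrix(0, length(rows), H, dimnames = list(ids, all_ids))
  s_in <- matrix(0, length(rows), n, dimnames = list(ids, colnames(X)))
  s_out <- matrix(0, length(rows), m, dimnames = list(ids, colnames(Y)))
  mu <- matrix(NA_real_, length(rows), m, dimnames = list(ids, colnames(Y)))
  vw <- matrix(NA_real_, length(rows), n, dimnames = list(ids, colnames(X)))
  u_free <- rep(NA_real_, length(rows))

  for (i in seq_along(rows)) {
    o <- rows[i]
    mult <- multiplier_weights(X, Y, o, model$rts, model$orientation, eps)
    if (eps > 0) {
      # explicit-epsilon mode: the multiplier optimum is the score
      radial[i] <- mult$value
      ph2 <- envelope_slacks(X, Y, o, model$rts, model$orientation,
                             envelope_radial(X, Y, o, model$rts,
                                             model$orientation)$radial)
    } else {
      ph1 <- envelope_radial(X, Y, o, model$rts, model$orientation)
      radial[i] <- ph1$radial
      ph2 <- envelope_slacks(X, Y, o, model$rts, model$orientation,
                             ph1$radial)
    }
    lambda[i, ] <- ph2$lambda
    s_in[i, ] <- ph2$slack_in
    s_out[i, ] <- ph2$slack_out
    mu[i, ] <- mult$mu
    vw[i, ] <- mult$v
    if (model$rts == "vrs") u_free[i] <- mult$u_free
  }

  scores <- if (model$orientation == "input") radial else 1 / radial
  names(scores) <- names(radial) <- ids
  # targets on the original data scale
  Xo <- input_matrix(table)[rows, , drop = FALSE]
  Yo <- output_matrix(table)[rows, , drop = FALSE]
  cx <- colMeans(input_matrix(table)); cy <- colMeans(output_matrix(table))
  t_in <- (if (model$orientation == "input") radial * Xo else Xo) -
    sweep(s_in, 2, cx, "*")
  t_out <- (if (model$orientation == "input") Yo else radial * Yo) +
    sweep(s_out, 2, cy, "*")
  benchmarks <- apply(lambda, 1, function(l) all_ids[l > 1e-6],
                      simplify = FALSE)
  structure(list(scores = scores, radial = radial, lambda = lambda,
                 slack_in = sweep(s_in, 2, cx, "*"),
                 slack_out = sweep(s_out, 2, cy, "*"),
                 targets = cbind(t_in, t_out),
                 benchmarks = benchmarks,
                 weights = list(mu = mu, v = vw, u_free = u_free),
                 model = model, ids = ids),
            class = "dea_result")
}

#' @export
print.dea_result <- function(x, digits = 6, ...) {
  print(x$model)
  cat(length(x$ids), "DMU(s);",
      sum(x$scores >= 1 - 1e-6), "efficient\n")
  print(round(x$scores, digits))
  invisible(x)
}

#' Efficient units of a solved DEA run
#'
#' @param result a [dea()] result.
#' @param tol efficiency tolerance; a DMU counts as efficient when its score
#'   is at least `1 - tol`.
#' @return vector of DMU ids.
#' @export
efficient_dmus <- function(result, tol = 1e-6) {
  stopifnot(inherits(result, "dea_result"))
  result$ids[result$scores >= 1 - tol]
}

#' Frontier projection targets
#'
#' Returns the projected (target) input/output vector per DMU: under input
#' orientation `(theta x - s_in, y + s_out)`, under output orientation
#' `(x - s_in, phi y + s_out)`. The same matrix is available as
#' `result$targets`; this accessor re-derives it from the peer combination
#' `lambda` as a consistency check and errors if the two disagree beyond
#' `tol` (relative to column scale).
#'
#' @param result a [dea()] result.
#' @param table the [dmu_table()] the result was solved on.
#' @param tol envelopment identity tolerance.
#' @return matrix of targets (inputs then outputs).
#' @export
projection_targets <- function(result, table, tol = 1e-6) {
  stopifnot(inherits(result, "dea_result"), is.dmu_table(table))
  if (result$model$frontier == "inverted") table <- invert_dmu_table(table)
  X <- input_matrix(table); Y <- output_matrix(table)
  combo <- cbind(result$lambda %*% X, result$lambda %*% Y)
  scale <- rep(pmax(colMeans(cbind(X, Y)), 1e-12), each = nrow(combo))
  if (max(abs(combo - result$targets) / scale) > tol)
    stop("envelopment identity violated beyond tolerance", call. = FALSE)
  result$targets
}
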