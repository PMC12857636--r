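# Damped, line-search-free limited-memory BFGS step engine.
#
# The chain-of-states effective force is not the gradient of any scalar
# objective (the spring and climbing projections see the whole band), so a
# generic scalar minimiser cannot drive it. This is the standard
# molecular-optimizer formulation: two-loop recursion over (s, y) pairs, an
# initial inverse-Hessian scale H0, and a per-atom step-length clip instead
# of a line search. One instance drives both structure relaxation and band
# optimization for determinism.

lbfgs_state <- function(history_size = 25, h0 = 1 / 70, max_step = 0.2) {
  env <- new.env(parent = emptyenv())
  env$s <- list(); env$y <- list()
  env$prev_x <- NULL; env$prev_g <- NULL
  env$history <- history_size; env$h0 <- h0; env$max_step <- max_step
  env
}

lbfgs_reset <- function(st) {
  st$s <- list(); st$y <- list()
  st$prev_x <- NULL; st$prev_g <- NULL
  invisible(st)
}

# g is the gradient (= -force); returns the step to add to x
lbfgs_step <- function(st, x, g) {
  if (!is.null(st$prev_x)) {
    s_new <- x - st$prev_x
    y_new <- g - st$prev_g
    sy <- sum(s_new * y_new)
    if (sy > 1e-12) {              # damped update: skip non-curvature pairs
      st$s <- c(st$s, list(s_new))
      st$y <- c(st$y, list(y_new))
      if (length(st$s) > st$history) {
        st$s <- st$s[-1]; st$y <- st$y[-1]
      }
    }
  }
  st$prev_x <- x; st$prev_g <- g
  q <- g
  k <- length(st$s)
  alpha <- numeric(k)
  rho <- numeric(k)
  if (k > 0) {
    for (i in k:1) {
      rho[i] <- 1 / sum(st$y[[i]] * st$s[[i]])
      alpha[i] <- rho[i] * sum(st$s[[i]] * q)
      q <- q - alpha[i] * st$y[[i]]
    }
  }
  # scale the initial inverse Hessian by the latest curvature pair
  # (gamma = s.y / y.y), falling back to the configured h0
  h0 <- st$h0
  if (k > 0) {
    yy <- sum(st$y[[k]]^2)
    if (yy > 0) h0 <- sum(st$s[[k]] * st$y[[k]]) / yy
  }
  z <- h0 * q
  if (k > 0) {
    for (i in 1:k) {
      beta <- rho[i] * sum(st$y[[i]] * z)
      z <- z + (alpha[i] - beta) * st$s[[i]]
    }
  }
  step <- -z
  # clip: no atom moves more than max_step
  pa <- matrix(step, ncol = 3, byrow = FALSE)
  lens <- sqrt(rowSums(pa^2))
  longest <- max(lens, 0)
  if (longest > st$max_step) step <- step * (st$max_step / longest)
  step
}

# max per-atom force norm of a flattened force vector (column-stacked n x 3)
fmax_of <- function(fvec) {
  fa <- matrix(fvec, ncol = 3, byrow = FALSE)
  sqrt(max(rowSums(fa^2)))
}
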