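# REML estimation of the animal model
#   y = mu + day + dam + u + e
# with u correlated through a pedigree or genomic relationship matrix and
# dam an IID common-environment effect. One generic linear-covariance
# AI-REML engine (V = sum_i theta_i V_i) serves the univariate and
# bivariate fits; average-information steps are safeguarded by step-halving
# and an EM-like scaled-gradient fallback, so the restricted log-likelihood
# never decreases across accepted iterations.

# Generic AI-REML for V(theta) = sum_i theta_i * Vlist[[i]].
# types: "var" (floored at floor_val) or "cov"; parents[[i]] gives, for a
# covariance parameter, the indices of its two variance parameters (used to
# keep the implied correlation inside (-1, 1) and to scale fallback steps).
.reml_engine <- function(y, X, Vlist, types, parents = NULL, init = NULL,
                         maxit = 100, tol = 1e-8, floor_frac = 1e-8,
                         verbose = FALSE) {
  n <- length(y)
  k <- length(Vlist)
  vy <- var(y)
  floor_val <- floor_frac * vy
  if (is.null(parents)) parents <- lapply(seq_len(k), function(i) c(i, i))

  clamp <- function(th) {
    th[types == "var"] <- pmax(th[types == "var"], floor_val)
    for (i in which(types == "cov")) {
      pa <- parents[[i]]
      lim <- 0.999 * sqrt(th[pa[1]] * th[pa[2]])
      th[i] <- max(min(th[i], lim), -lim)
    }
    th
  }

  eval_at <- function(th) {
    V <- matrix(0, n, n)
    for (i in seq_len(k)) V <- V + th[i] * Vlist[[i]]
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(NULL)
    Vinv <- chol2inv(L)
    VinvX <- Vinv %*% X
    XtVinvX <- crossprod(X, VinvX)
    Cf <- tryCatch(solve(XtVinvX), error = function(e) NULL)
    if (is.null(Cf)) return(NULL)
    P <- Vinv - VinvX %*% Cf %*% t(VinvX)
    Py <- drop(P %*% y)
    ldV <- 2 * sum(log(diag(L)))
    ldX <- as.numeric(determinant(XtVinvX, logarithm = TRUE)$modulus)
    logL <- -0.5 * (ldV + ldX + sum(y * Py))
    list(V = V, Vinv = Vinv, VinvX = VinvX, Cf = Cf, P = P, Py = Py, logL = logL)
  }

  theta <- clamp(init %||% {
    nv <- sum(types == "var")
    th0 <- numeric(k)
    th0[types == "var"] <- vy / nv
    th0
  })

  st <- eval_at(theta)
  if (is.null(st)) stopf("initial variance components give a singular model")
  trajectory <- data.frame(iter = 0, logL = st$logL,
                           t(setNames(theta, paste0("theta", seq_len(k)))))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    # gradient and average information
    W <- matrix(0, n, k)
    grad <- numeric(k)
    for (i in seq_len(k)) {
      Wi <- Vlist[[i]] %*% st$Py
      W[, i] <- Wi
      grad[i] <- -0.5 * (sum(st$P * Vlist[[i]]) - sum(st$Py * Wi))
    }
    AI <- 0.5 * crossprod(W, st$P %*% W)
    delta <- tryCatch(solve(AI + diag(1e-8 * max(diag(AI), 1), k), grad),
                      error = function(e) grad / max(diag(AI), 1))

    accepted <- FALSE
    step <- 1
    for (half in 1:12) {
      cand <- clamp(theta + step * delta)
      stc <- eval_at(cand)
      if (!is.null(stc) && stc$logL >= st$logL - 1e-10) {
        accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) {
      # EM-like scaled-gradient fallback: guaranteed-direction uphill step
      scale <- vapply(seq_len(k), function(i) {
        pa <- parents[[i]]
        max(theta[pa[1]] * theta[pa[2]], floor_val^2)
      }, numeric(1))
      step <- 1
      for (half in 1:20) {
        cand <- clamp(theta + step * 2 * scale / n * grad)
        stc <- eval_at(cand)
        if (!is.null(stc) && stc$logL >= st$logL - 1e-10) {
          accepted <- TRUE; break
        }
        step <- step / 2
      }
    }
    if (!accepted) { converged <- TRUE; break } # stationary: no uphill direction

    rel_change <- max(abs(cand - theta) / (abs(theta) + 1e-6))
    theta <- cand
    st <- stc
    trajectory <- rbind(trajectory,
                        data.frame(iter = it, logL = st$logL,
                                   t(setNames(theta, paste0("theta", seq_len(k))))))
    if (verbose) message(sprintf("iter %d logL %.6f", it, st$logL))
    if (rel_change < tol) { converged <- TRUE; break }
  }

  # final gradient / AI for standard errors and the stationarity check
  W <- matrix(0, n, k)
  grad <- numeric(k)
  for (i in seq_len(k)) {
    W[, i] <- Vlist[[i]] %*% st$Py
    grad[i] <- -0.5 * (sum(st$P * Vlist[[i]]) - sum(st$Py * W[, i]))
  }
  AI <- 0.5 * crossprod(W, st$P %*% W)
  ai_inv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, k, k))
  boundary <- types == "var" & theta <= floor_val * (1 + 1e-6)
  if (!converged) {
    # a stationary point can also be declared from the projected gradient
    # (boundary components pushing outward do not count)
    g_proj <- grad
    g_proj[boundary & grad < 0] <- 0
    if (max(abs(g_proj)) < 1e-4 * n) converged <- TRUE
  }

  list(theta = theta, logL = st$logL, ai_inv = ai_inv, Py = st$Py,
       beta = drop(st$Cf %*% crossprod(st$VinvX, y)),
       beta_cov = st$Cf,
       converged = converged, boundary = boundary,
       iterations = max(trajectory$iter), trajectory = trajectory)
}

#' REML fit of the maternal-effect animal model
#'
#' Fits `trait = day + dam + animal + residual` by AI-REML, where the
#' animal effect is correlated through the supplied relationship matrix
#' (pedigree A or genomic G) and the dam effect is an IID random effect.
#' With two traits a bivariate model is fitted; the residual covariance is
#' estimated when the traits share phenotyped animals and fixed at zero
#' when they are measured on disjoint individuals (which are then linked
#' only through the relationship matrix).
#'
#' @param phenotypes `data.frame` with an `id` column, the trait column(s),
#'   and the fixed/dam factor columns.
#' @param traits one or two trait column names.
#' @param kinship relationship matrix covering all phenotyped animals.
#' @param fixed fixed-factor column (day/group of phenotyping), or `NULL`
#'   for an intercept-only model; for bivariate fits either one column
#'   name used for both traits or a vector of length two.
#' @param dam_col dam column name.
#' @param dam_traits traits for which the IID dam effect is fitted;
#'   defaults to the trait named `"tle"` (the resistance phenotype), the
#'   only trait for which a maternal effect is retained by default.
#' @param maxit,tol iteration cap and relative-change convergence
#'   tolerance.
#' @param verbose print the log-likelihood path.
#' @return object of class `reml_fit` with elements `varcomp` (named
#'   estimates + SEs), `h2`, `h2_se`, `dam_ratio`, `dam_ratio_se`, `rg`,
#'   `rg_se` (bivariate), `logL`, `AIC`, `n_param`, `converged`,
#'   `boundary`, `fixef` (day-effect estimates), `dam_blup`, `u_blup`,
#'   `trajectory`.
#' @export
reml_fit <- function(phenotypes, traits, kinship, fixed = "group",
                     dam_col = "dam", dam_traits = intersect("tle", traits),
                     maxit = 100, tol = 1e-8, verbose = FALSE) {
  if (!length(traits) %in% 1:2) stopf("one or two traits required")
  if (length(fixed) == 1) fixed <- rep(fixed, length(traits))

  obs <- lapply(traits, function(tr) which(is.finite(phenotypes[[tr]])))
  ids <- lapply(obs, function(i) phenotypes$id[i])
  for (t in seq_along(traits)) {
    missing_k <- setdiff(ids[[t]], rownames(kinship))
    if (length(missing_k))
      stopf("%d phenotyped animals missing from the relationship matrix", length(missing_k))
  }

  y <- unlist(lapply(seq_along(traits), function(t) phenotypes[[traits[t]]][obs[[t]]]))
  ns <- lengths(obs)
  n <- sum(ns)
  block <- rep(seq_along(traits), ns)

  # fixed design: per-trait intercept + day deviations
  Xs <- lapply(seq_along(traits), function(t) {
    if (is.null(fixed[t]) || is.na(fixed[t])) return(matrix(1, ns[t], 1))
    f <- factor(phenotypes[[fixed[t]]][obs[[t]]])
    if (nlevels(f) < 2) matrix(1, ns[t], 1) else stats::model.matrix(~f)
  })
  q <- vapply(Xs, ncol, integer(1))
  X <- matrix(0, n, sum(q))
  off <- c(0, cumsum(q))
  for (t in seq_along(traits)) X[block == t, (off[t] + 1):off[t + 1]] <- Xs[[t]]

  # covariance structures
  Ks <- lapply(seq_along(traits), function(t) kinship[ids[[t]], ids[[t]], drop = FALSE])
  Vlist <- list(); types <- character(0); parents <- list()
  labels <- character(0); comp_trait <- list()
  add_comp <- function(V, type, label, tr, pa = NULL) {
    j <- length(Vlist) + 1
    Vlist[[j]] <<- V
    types[j] <<- type
    labels[j] <<- label
    comp_trait[[j]] <<- tr # trait indices the component scales with
    parents[[j]] <<- pa %||% c(j, j)
  }
  embed <- function(M, t1, t2) {
    V <- matrix(0, n, n)
    V[block == t1, block == t2] <- M
    if (t1 != t2) V[block == t2, block == t1] <- t(M)
    V
  }

  if (length(traits) == 1) {
    add_comp(embed(Ks[[1]], 1, 1), "var", "var_u", c(1, 1))
  } else {
    add_comp(embed(Ks[[1]], 1, 1), "var", paste0("var_u_", traits[1]), c(1, 1))
    add_comp(embed(Ks[[2]], 2, 2), "var", paste0("var_u_", traits[2]), c(2, 2))
    K12 <- kinship[ids[[1]], ids[[2]], drop = FALSE]
    add_comp(embed(K12, 1, 2), "cov", "cov_u", c(1, 2), pa = c(1, 2))
  }

  dam_W <- list()
  for (t in seq_along(traits)) {
    if (traits[t] %in% dam_traits) {
      dmf <- factor(phenotypes[[dam_col]][obs[[t]]])
      if (nlevels(dmf) < 2) stopf("dam effect requested but fewer than two dams")
      W <- stats::model.matrix(~ 0 + dmf)
      add_comp(embed(tcrossprod(W), t, t), "var", paste0("var_dam_", traits[t]), c(t, t))
      dam_W[[as.character(t)]] <- W
    }
  }

  ie <- integer(0)
  for (t in seq_along(traits)) {
    add_comp(embed(diag(ns[t]), t, t), "var", paste0("var_e_", traits[t]), c(t, t))
    ie <- c(ie, length(Vlist))
  }
  shared <- if (length(traits) == 2) intersect(ids[[1]], ids[[2]]) else character(0)
  if (length(shared)) {
    M <- matrix(0, ns[1], ns[2])
    M[cbind(match(shared, ids[[1]]), match(shared, ids[[2]]))] <- 1
    add_comp(embed(M, 1, 2), "cov", "cov_e", c(1, 2), pa = ie)
  }

  # scale traits to unit variance for numerical conditioning, back-transform after
  sc <- vapply(seq_along(traits), function(t) sd(y[block == t]), numeric(1))
  ysc <- y / sc[block]
  fit <- .reml_engine(ysc, X, Vlist, types, parents, maxit = maxit, tol = tol,
                      verbose = verbose)

  mult <- vapply(comp_trait, function(tr) sc[tr[1]] * sc[tr[2]], numeric(1))
  theta <- fit$theta * mult
  se <- sqrt(pmax(diag(fit$ai_inv), 0)) * mult
  names(theta) <- names(se) <- labels
  Vth <- fit$ai_inv * tcrossprod(mult)

  delta_se <- function(gfun) {
    g <- gfun(theta)
    as.numeric(sqrt(pmax(t(g) %*% Vth %*% g, 0)))
  }

  out <- list(traits = traits, varcomp = theta, se = se, logL = fit$logL,
              n_param = length(theta),
              AIC = -2 * fit$logL + 2 * length(theta),
              converged = fit$converged,
              boundary = setNames(fit$boundary, labels),
              iterations = fit$iterations, trajectory = fit$trajectory,
              n_obs = ns)

  if (length(traits) == 1) {
    idx_all <- seq_along(theta)
    sp <- sum(theta)
    out$sigma_p2 <- sp
    out$h2 <- theta[[1]] / sp
    out$h2_se <- delta_se(function(th) {
      g <- rep(-th[[1]] / sp^2, length(th)); g[1] <- (sp - th[[1]]) / sp^2; g
    })
    di <- grep("^var_dam", labels)
    if (length(di)) {
      out$dam_ratio <- theta[[di]] / sp
      out$dam_ratio_se <- delta_se(function(th) {
        g <- rep(-th[[di]] / sp^2, length(th)); g[di] <- (sp - th[[di]]) / sp^2; g
      })
    }
  } else {
    vu1 <- theta[[1]]; vu2 <- theta[[2]]; cu <- theta[[3]]
    out$rg <- cu / sqrt(vu1 * vu2)
    out$rg_se <- delta_se(function(th) {
      g <- numeric(length(th))
      g[1] <- -cu / (2 * sqrt(vu1^3 * vu2))
      g[2] <- -cu / (2 * sqrt(vu2^3 * vu1))
      g[3] <- 1 / sqrt(vu1 * vu2)
      g
    })
    out$h2 <- setNames(c(vu1, vu2) /
                         c(sum(theta[grep(paste0("_", traits[1], "$"), labels)]),
                           sum(theta[grep(paste0("_", traits[2], "$"), labels)])),
                       traits)
  }

  # BLUEs / BLUPs on the original scale
  Py <- fit$Py # from scaled fit; u = theta_sc * K %*% Py_sc, rescale
  beta <- fit$beta
  fx <- list()
  for (t in seq_along(traits)) {
    b <- beta[(off[t] + 1):off[t + 1]] * sc[t]
    f <- if (!is.null(fixed[t]) && !is.na(fixed[t])) factor(phenotypes[[fixed[t]]][obs[[t]]]) else NULL
    if (!is.null(f)) {
      eff <- c(0, b[-1]) + b[1] # per-level means
      names(eff) <- levels(f)
      fx[[traits[t]]] <- eff
    } else {
      fx[[traits[t]]] <- b
    }
  }
  out$fixef <- fx

  # genetic BLUPs for phenotyped animals of trait 1 (univariate case)
  if (length(traits) == 1) {
    usc <- fit$theta[1] * (Ks[[1]] %*% Py)
    out$u_blup <- setNames(drop(usc) * sc[1], ids[[1]])
    di <- grep("^var_dam", labels)
    if (length(di)) {
      W <- dam_W[["1"]]
      dsc <- fit$theta[di] * crossprod(W, Py)
      out$dam_blup <- setNames(drop(dsc) * sc[1], sub("^dmf", "", rownames(dsc)))
    }
  }

  class(out) <- "reml_fit"
  out
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML animal model (%s): logL = %.3f, AIC = %.1f%s\n",
              paste(x$traits, collapse = " x "), x$logL, x$AIC,
              if (x$converged) "" else " [NOT CONVERGED]"))
  vc <- data.frame(estimate = x$varcomp, se = x$se, boundary = x$boundary)
  print(round(vc, 5))
  if (length(x$traits) == 1) {
    cat(sprintf("h2 = %.3f (SE %.3f)", x$h2, x$h2_se))
    if (!is.null(x$dam_ratio))
      cat(sprintf(", dam ratio = %.3f (SE %.3f)", x$dam_ratio, x$dam_ratio_se))
    cat("\n")
  } else {
    cat(sprintf("r_g = %.3f (SE %.3f)\n", x$rg, x$rg_se))
  }
  invisible(x)
}

#' Compare two REML fits by AIC
#'
#' AIC = -2 logL + 2 x (number of variance parameters). The lower AIC wins;
#' on an exact tie the model with fewer parameters is kept.
#'
#' @param fit_a,fit_b `reml_fit` objects on the same data and fixed
#'   effects (checked via the number of observations).
#' @return list with `selected` (1 or 2), `fit` (the winning object),
#'   `delta_aic` (AIC_a - AIC_b).
#' @export
aic_compare <- function(fit_a, fit_b) {
  if (!identical(fit_a$n_obs, fit_b$n_obs))
    stopf("fits are not on the same data (observation counts differ)")
  d <- fit_a$AIC - fit_b$AIC
  sel <- if (d < 0) 1L else if (d > 0) 2L else if (fit_a$n_param <= fit_b$n_param) 1L else 2L
  list(selected = sel, fit = if (sel == 1L) fit_a else fit_b, delta_aic = d)
}

#' Write a variance-component fit report to TSV
#'
#' @param fit a `reml_fit`.
#' @param path output path.
#' @export
write_reml_report <- function(fit, path) {
  df <- data.frame(component = names(fit$varcomp), estimate = fit$varcomp,
                   se = fit$se, boundary = fit$boundary)
  extra <- data.frame(component = c("logL", "AIC", "converged"),
                      estimate = c(fit$logL, fit$AIC, as.numeric(fit$converged)),
                      se = NA_real_, boundary = NA)
  if (length(fit$traits) == 1) {
    extra <- rbind(extra, data.frame(component = "h2", estimate = fit$h2,
                                     se = fit$h2_se, boundary = NA))
    if (!is.null(fit$dam_ratio))
      extra <- rbind(extra, data.frame(component = "dam_ratio",
                                       estimate = fit$dam_ratio,
                                       se = fit$dam_ratio_se, boundary = NA))
  } else {
    extra <- rbind(extra, data.frame(component = "r_g", estimate = fit$rg,
                                     se = fit$rg_se, boundary = NA))
  }
  .write_tsv(rbind(df, extra), path)
}
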