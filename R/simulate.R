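# Integration of the assembled system and result containers.

#' Simulate a built PBPK model
#'
#' Two integration paths share the same model matrix:
#' \describe{
#'   \item{`"expm"`}{exact matrix-exponential propagation on the output grid.
#'     The system is linear and time-invariant between dose events, so the
#'     one-step transition matrix is computed once per distinct step size and
#'     states are propagated to machine precision.  Default without a DDI
#'     scenario.}
#'   \item{`"lsoda"`}{stiff-capable \pkg{deSolve} integration with dose events
#'     as discontinuities, required when a perpetrator makes enzyme activity
#'     time-varying, and available generally for tolerance-convergence
#'     checks.}
#' }
#'
#' @param object a `pbpk_model`.
#' @param nsim,seed unused (kept for the [stats::simulate()] signature).
#' @param t_end_h end of simulation, h; must exceed the last dose time.
#' @param dt_h output grid step, h.
#' @param method `"auto"`, `"expm"` or `"lsoda"`.
#' @param rtol,atol solver tolerances (lsoda path).
#' @param ... ignored.
#' @return object of class `pbpk_sim`: `time_h`, an `observables` data.frame
#'   in long format (`time_h`, `analyte`, `matrix`, `concentration_mg_L`),
#'   the state `amounts` matrix (mg), cumulative dosed base amounts, and the
#'   model.
#' @export
simulate.pbpk_model <- function(object, nsim = 1, seed = NULL,
                                t_end_h = 240, dt_h = NULL,
                                method = c("auto", "expm", "lsoda"),
                                rtol = NULL, atol = NULL, ...) {
  method <- match.arg(method)
  cfg <- object$config
  dt_h <- dt_h %||% cfg$dt_h
  rtol <- rtol %||% cfg$rtol
  atol <- atol %||% cfg$atol
  if (nrow(object$events)) {
    # doses beyond the horizon are simply not administered (truncated run)
    object$events <- object$events[object$events$time_h < t_end_h, ,
                                   drop = FALSE]
    if (!nrow(object$events))
      warning("no dose event falls inside the simulated horizon")
  }
  if (method == "auto")
    method <- if (is.null(object$interactions)) "expm" else "lsoda"
  if (method == "expm" && !is.null(object$interactions))
    stop("matrix-exponential path requires a time-invariant system; ",
         "use method = 'lsoda' for DDI scenarios")

  grid <- sort(unique(c(seq(0, t_end_h, by = dt_h), object$events$time_h,
                        t_end_h)))
  n <- length(object$states)
  out <- matrix(0, length(grid), n,
                dimnames = list(NULL, object$states))

  if (method == "expm") {
    y <- numeric(n)
    ev <- object$events
    prop_cache <- new.env(parent = emptyenv())
    stepmat <- function(h) {
      key <- format(h, digits = 15)
      if (is.null(prop_cache[[key]]))
        prop_cache[[key]] <- as.matrix(Matrix::expm(object$A * h))
      prop_cache[[key]]
    }
    for (i in seq_along(grid)) {
      if (i > 1) {
        h <- grid[i] - grid[i - 1]
        y <- stepmat(h) %*% y
      }
      out[i, ] <- y            # pre-event value at dose times
      hit <- which(abs(ev$time_h - grid[i]) < 1e-9)
      for (k in hit) y[ev$state[k]] <- y[ev$state[k]] + ev$amount_mg[k]
    }
  } else {
    rhs <- make_rhs(object)
    y0 <- stats::setNames(numeric(n + rhs$n_extra),
                          c(object$states, rhs$extra_names))
    if (rhs$n_extra) y0[rhs$extra_names] <- 1  # active enzyme fractions
    ev <- object$events
    evdf <- NULL
    if (nrow(ev)) {
      evdf <- data.frame(var = object$states[ev$state], time = ev$time_h,
                         value = ev$amount_mg, method = "add")
      # deSolve requires event times present in the output times
      grid <- sort(unique(c(grid, ev$time_h)))
    }
    sol <- deSolve::lsoda(y = y0, times = grid, func = rhs$func, parms = NULL,
                          rtol = rtol, atol = atol,
                          jacfunc = rhs$jac,
                          jactype = if (is.null(rhs$jac)) "fullint" else "fullusr",
                          events = if (is.null(evdf)) NULL else list(data = evdf),
                          maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failure at t = ", max(sol[, 1]),
           "; final state snapshot: ",
           paste(utils::head(signif(sol[nrow(sol), -1], 3), 10), collapse = ", "))
    out <- sol[, 1 + seq_len(n), drop = FALSE]
    colnames(out) <- object$states
    if (rhs$n_extra) {
      enzyme_activity <- sol[, n + 1 + seq_len(rhs$n_extra), drop = FALSE]
      colnames(enzyme_activity) <- rhs$extra_names
    }
  }
  if (!exists("enzyme_activity", inherits = FALSE)) enzyme_activity <- NULL

  dosed <- vapply(grid, function(t)
    sum(object$events$amount_mg[object$events$time_h <= t - 1e-9]) +
      # a dose at exactly t is recorded post-observation
      0, numeric(1))

  structure(list(
    time_h = grid,
    amounts = out,
    dosed_cum_mg = dosed,
    observables = extract_observables(object, grid, out),
    enzyme_activity = enzyme_activity,
    model = object,
    method = method
  ), class = "pbpk_sim")
}

make_rhs <- function(model) {
  A <- model$A
  ix <- model$index
  ddi <- model$interactions
  if (is.null(ddi)) {
    return(list(func = function(t, y, p) list(A %*% y),
                jac = function(t, y, p) A,
                n_extra = 0, extra_names = character()))
  }
  perp <- ddi$perpetrator
  affected <- names(perp$ki_u)
  affected <- union(affected, names(perp$kinact))
  affected <- intersect(affected, names(model$enzyme_flux_coef))
  e_names <- paste0("E_", affected)
  coefs <- model$enzyme_flux_coef[affected]
  li <- ix["p_liver"]
  has_met <- !is.null(model$metabolite)
  ffr <- stats::setNames(numeric(length(affected)), affected)
  if (has_met) {
    mw_ratio <- model$metabolite$molecular_weight_base /
      model$parent$molecular_weight_base
    for (e in affected) {
      for (lk in model$parent$metabolite_links)
        if (lk$enzyme == e && lk$product == model$metabolite$name)
          ffr[e] <- lk$formation_fraction * mw_ratio
    }
  }
  nv <- length(model$states)
  jac <- function(t, y, p) {
    N <- nv + length(affected)
    M <- matrix(0, N, N)
    M[seq_len(nv), seq_len(nv)] <- A
    iu <- perpetrator_concentration(perp, t)
    for (j in seq_along(affected)) {
      e <- affected[j]
      cm <- competitive_multiplier(iu, perp$ki_u[[e]] %||% Inf)
      E <- y[nv + j]
      dm <- (E * cm - 1) * coefs[[e]]
      rows <- c(li, ix[paste0("p_elim_", e)])
      wts <- c(-1, 1)
      if (has_met && ffr[[e]] > 0) {
        rows <- c(rows, ix["m_liver"], ix["m_formed"])
        wts <- c(wts, ffr[[e]], ffr[[e]])
      }
      M[rows, li] <- M[rows, li] + wts * dm
      M[rows, nv + j] <- wts * cm * coefs[[e]] * y[li]
      kd <- perp$kdeg[[e]] %||% perp$kdeg_default
      inact <- if (!is.null(perp$kinact[[e]]))
        perp$kinact[[e]] * iu / (perp$KI_u[[e]] + iu) else 0
      M[nv + j, nv + j] <- -(kd + inact)
    }
    M
  }
  func <- function(t, y, p) {
    yv <- y[seq_len(nv)]
    dy <- as.numeric(A %*% yv)
    dE <- numeric(length(affected))
    iu <- perpetrator_concentration(perp, t)
    for (j in seq_along(affected)) {
      e <- affected[j]
      E <- y[nv + j]
      mult <- E * competitive_multiplier(iu, perp$ki_u[[e]] %||% Inf)
      dflux <- (mult - 1) * coefs[[e]] * yv[li]
      dy[li] <- dy[li] + -dflux
      dy[ix[paste0("p_elim_", e)]] <- dy[ix[paste0("p_elim_", e)]] + dflux
      if (has_met && ffr[[e]] > 0) {
        dy[ix["m_liver"]] <- dy[ix["m_liver"]] + ffr[[e]] * dflux
        dy[ix["m_formed"]] <- dy[ix["m_formed"]] + ffr[[e]] * dflux
      }
      if (!is.null(perp$kinact[[e]])) {
        dE[j] <- mbi_turnover(E, iu, perp$KI_u[[e]], perp$kinact[[e]],
                              perp$kdeg[[e]] %||% perp$kdeg_default)
      } else {
        dE[j] <- (perp$kdeg[[e]] %||% perp$kdeg_default) * (1 - E)
      }
    }
    list(c(dy, dE))
  }
  list(func = func, jac = jac, n_extra = length(affected),
       extra_names = e_names)
}

extract_observables <- function(model, grid, out) {
  ix <- model$index
  vols <- model$individual$organ_volumes
  res <- list()
  add <- function(analyte, matrix_, conc)
    res[[length(res) + 1]] <<- data.frame(
      time_h = grid, analyte = analyte, matrix = matrix_,
      concentration_mg_L = as.numeric(conc))
  bp_p <- model$parent$blood_plasma_ratio
  cb <- out[, ix["p_ven"]] / vols["venous"]
  add(model$parent$name, "blood", cb)
  add(model$parent$name, "plasma", cb / bp_p)
  v_lung <- vols["lung_EC"] + vols["lung_IC"]
  add(model$parent$name, "lung_tissue",
      (out[, ix["p_lungEC"]] + out[, ix["p_lungIC"]]) / v_lung)
  if (!is.null(model$metabolite)) {
    bp_m <- model$metabolite$blood_plasma_ratio
    cbm <- out[, ix["m_ven"]] / vols["venous"]
    add(model$metabolite$name, "blood", cbm)
    add(model$metabolite$name, "plasma", cbm / bp_m)
    add(model$metabolite$name, "lung_tissue", out[, ix["m_lung"]] / v_lung)
  }
  do.call(rbind, res)
}

#' Extract one observable series from a simulation
#'
#' @param sim a `pbpk_sim`.
#' @param analyte analyte name (default: parent).
#' @param matrix one of `"plasma"`, `"blood"`, `"lung_tissue"`.
#' @return data.frame `time_h`, `conc` (mg/L).
#' @export
observable <- function(sim, analyte = NULL, matrix = "plasma") {
  analyte <- analyte %||% sim$model$parent$name
  ob <- sim$observables
  sel <- ob$analyte == analyte & ob$matrix == matrix
  if (!any(sel)) stop("no observable for ", analyte, "/", matrix)
  data.frame(time_h = ob$time_h[sel], conc = ob$concentration_mg_L[sel])
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat("<pbpk_sim> ", x$model$parent$name, ", 0-",
      max(x$time_h), " h (", length(x$time_h), " points, method ",
      x$method, ")\n", sep = "")
  pl <- observable(x, matrix = "plasma")
  cat(sprintf("  parent plasma Cmax %.4g mg/L at %.2f h\n",
              max(pl$conc), pl$time_h[which.max(pl$conc)]))
  invisible(x)
}

#' @export
plot.pbpk_sim <- function(x, matrices = c("plasma", "lung_tissue"),
                          log = "y", ...) {
  pl <- lapply(matrices, function(m) observable(x, matrix = m))
  ymin <- max(min(unlist(lapply(pl, function(d) d$conc[d$conc > 0]))), 1e-6)
  ymax <- max(unlist(lapply(pl, function(d) d$conc)))
  graphics::plot(NA, xlim = range(x$time_h), ylim = c(ymin, ymax), log = log,
                 xlab = "time (h)", ylab = "concentration (mg/L)", ...)
  for (i in seq_along(pl))
    graphics::lines(pl[[i]]$time_h, pmax(pl[[i]]$conc, ymin), col = i, lty = i)
  graphics::legend("topright", legend = matrices, col = seq_along(pl),
                   lty = seq_along(pl), bty = "n")
  invisible(x)
}

#' Worst-case mass-balance error of a simulation
#'
#' At every output time the cumulative dosed base amount must equal the sum
#' of all parent compartment amounts, the unabsorbed sink and the per-pathway
#' eliminated amounts; the metabolite ledger must likewise balance against
#' its cumulative formed amount.  Returns the maximum relative deviation.
#'
#' @param result a `pbpk_sim`.
#' @return maximum relative mass-balance error (dimensionless).
#' @export
mass_balance <- function(result) {
  model <- result$model
  ix <- model$index
  p_states <- grep("^p_", model$states, value = TRUE)
  tot_p <- rowSums(result$amounts[, p_states, drop = FALSE])
  denom <- pmax(result$dosed_cum_mg, max(result$dosed_cum_mg) * 1e-6, 1e-12)
  err_p <- abs(tot_p - result$dosed_cum_mg) / denom
  err <- max(err_p)
  if (!is.null(model$metabolite)) {
    m_states <- setdiff(grep("^m_", model$states, value = TRUE), "m_formed")
    tot_m <- rowSums(result$amounts[, m_states, drop = FALSE])
    formed <- result$amounts[, "m_formed"]
    denom_m <- pmax(formed, max(formed) * 1e-6, 1e-12)
    err <- max(err, abs(tot_m - formed) / denom_m)
  }
  err
}

#' Lung-tissue to plasma partition ratio at a time point
#'
#' @param result a `pbpk_sim` containing plasma and lung observables.
#' @param t_h time, h (must lie on the output grid).
#' @param analyte analyte name (default parent).
#' @return dimensionless Kp at `t_h`.
#' @export
lung_kp <- function(result, t_h, analyte = NULL) {
  pl <- observable(result, analyte, "plasma")
  lu <- observable(result, analyte, "lung_tissue")
  i <- which.min(abs(pl$time_h - t_h))
  if (abs(pl$time_h[i] - t_h) > 1e-6)
    stop("time ", t_h, " h is not on the simulation grid")
  if (pl$conc[i] <= 0) stop("plasma concentration is zero at t = ", t_h)
  lu$conc[i] / pl$conc[i]
}

#' Write a simulation result as tidy delimited text
#'
#' Emits the long observable table (`time_h`, `analyte`, `matrix`,
#' `concentration_mg_L`) preceded by a commented metadata header (resolved
#' key parameters).
#'
#' @param sim a `pbpk_sim`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  md <- c(
    paste0("# analyte: ", sim$model$parent$name),
    paste0("# metabolite: ",
           if (is.null(sim$model$metabolite)) "none"
           else sim$model$metabolite$name),
    paste0("# regimen: ", sim$model$regimen$label),
    paste0("# method: ", sim$method),
    paste0("# fm: ", paste(sprintf("%s=%.3f", names(sim$model$parent$fm_map),
                                   sim$model$parent$fm_map), collapse = " ")),
    paste0("# formation_fractions: ",
           paste(vapply(sim$model$parent$metabolite_links,
                        function(l) sprintf("%s=%.2f", l$enzyme,
                                            l$formation_fraction),
                        character(1)), collapse = " "))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(md, con)
  utils::write.table(sim$observables, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
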