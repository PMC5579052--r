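## Standard modelling-object methods for the "qce" isobar object.

#' @export
as.data.frame.qce <- function(x, ..., populations = TRUE) {
  V <- vapply(x$states, `[[`, numeric(1), "molar_volume")
  kw <- kw_curve(x)
  df <- data.frame(
    T = x$T,
    p = x$p,
    molar_volume = V,
    density = x$cluster_set$monomer$molar_mass / (1000 * V),  # g/cm^3
    phase = vapply(x$states, `[[`, character(1), "phase"),
    gibbs_energy = vapply(x$states, `[[`, numeric(1), "gibbs_energy"),
    Kw = kw$Kw, pKw = kw$pKw,
    converged = vapply(x$states, `[[`, logical(1), "converged"))
  if (populations) {
    pops <- do.call(rbind, lapply(x$states, `[[`, "populations"))
    colnames(pops) <- paste0("N_", colnames(pops))
    df <- cbind(df, as.data.frame(pops))
  }
  df
}

#' @export
print.qce <- function(x, ...) {
  cat(sprintf("QCE isobar of '%s': %d temperatures in [%.2f, %.2f] K at %.4g Pa\n",
              x$cluster_set$name, length(x$T), min(x$T), max(x$T), x$p))
  print(x$params)
  tt <- x$transition_temperature
  cat(if (is.na(tt)) "no phase transition detected on the grid\n"
      else sprintf("phase transition (boiling) at %.2f K\n", tt))
  invisible(x)
}

#' @export
coef.qce <- function(object, ...) {
  c(a_mf = object$params$a_mf, b_xv = object$params$b_xv)
}

#' @export
summary.qce <- function(object, ...) {
  df <- as.data.frame(object, populations = FALSE)
  near <- function(Tq) df[which.min(abs(df$T - Tq)), ]
  structure(list(name = object$cluster_set$name,
                 params = coef(object), p = object$p,
                 T_range = range(df$T),
                 transition_temperature = object$transition_temperature,
                 at_298 = near(298.15),
                 pKw_range = range(df$pKw[is.finite(df$pKw)]),
                 n_liquid = sum(df$phase == "liquid-like"),
                 n_points = nrow(df)),
            class = "summary.qce")
}

#' @export
print.summary.qce <- function(x, ...) {
  cat(sprintf("QCE isobar summary ('%s', p = %.4g Pa)\n", x$name, x$p))
  cat(sprintf("  a_mf = %.6g J L/mol^2, b_xv = %.6g\n",
              x$params["a_mf"], x$params["b_xv"]))
  cat(sprintf("  %d grid points in [%.2f, %.2f] K; %d liquid-like\n",
              x$n_points, x$T_range[1], x$T_range[2], x$n_liquid))
  cat(if (is.na(x$transition_temperature))
    "  no boiling transition on the grid\n"
    else sprintf("  boiling transition at %.2f K\n", x$transition_temperature))
  a <- x$at_298
  cat(sprintf("  nearest 298.15 K (T = %.2f): density %.4f g/cm^3, phase %s",
              a$T, a$density, a$phase))
  if (is.finite(a$pKw)) cat(sprintf(", pKw %.2f", a$pKw))
  cat("\n")
  if (all(is.finite(x$pKw_range)))
    cat(sprintf("  pKw range on grid: %.2f .. %.2f\n",
                x$pKw_range[1], x$pKw_range[2]))
  invisible(x)
}

#' Predict QCE observables at new temperatures
#'
#' Re-converges the model at the requested temperatures (same cluster set,
#' parameters and pressure as the fitted isobar object).
#'
#' @param object A \code{"qce"} object.
#' @param T Temperatures in K (default: the object's own grid).
#' @param ... Unused.
#' @return Data frame as from \code{as.data.frame(qce(...))}.
#' @export
predict.qce <- function(object, T = object$T, ...) {
  Ts <- sort(unique(as.numeric(T)))
  sub <- qce(object$cluster_set, object$params, T = Ts, p = object$p,
             include_zpe = object$include_zpe, scale = object$scale)
  as.data.frame(sub, populations = FALSE)
}

#' Plot a QCE isobar
#'
#' Two base-graphics panels: mass density against temperature and, when the
#' cluster set contains ion-pair clusters, pKw against temperature with the
#' packaged experimental reference points overlaid. A detected boiling
#' transition is marked with a dashed vertical line.
#'
#' @param x A \code{"qce"} object.
#' @param ... Passed on to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @export
plot.qce <- function(x, ...) {
  df <- as.data.frame(x, populations = FALSE)
  has_kw <- any(is.finite(df$pKw))
  old <- graphics::par(mfrow = c(1L + has_kw, 1L), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  plot(df$T, df$density, type = "l", xlab = "T / K",
       ylab = expression(rho ~ "/ g" ~ cm^-3), ...)
  if (!is.na(x$transition_temperature))
    graphics::abline(v = x$transition_temperature, lty = 2, col = "grey40")
  if (has_kw) {
    plot(df$T, df$pKw, type = "l", xlab = "T / K", ylab = "pKw", ...)
    ref <- pkw_experimental_reference()
    graphics::points(ref$T, ref$pKw, pch = 4, col = "red3")
    if (!is.na(x$transition_temperature))
      graphics::abline(v = x$transition_temperature, lty = 2, col = "grey40")
  }
  invisible(x)
}
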