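#' @include AllClasses.R
NULL

#' Hill saturation binding model
#'
#' Predicted change in fluorescence anisotropy at total protein
#' concentration \code{E}:
#' \deqn{\Delta A = \Delta A_T \, \frac{E^H}{K_d^H + E^H}}
#' with dissociation constant \code{kd} (same unit as \code{E}), Hill
#' coefficient \code{h} and total anisotropy change \code{deltaAT}. The
#' curve rises monotonically from 0 at \code{E = 0} towards \code{deltaAT},
#' passing exactly half-saturation at \code{E = kd} for any \code{h}.
#'
#' @param E total protein concentration(s), >= 0.
#' @param kd dissociation constant, > 0.
#' @param h Hill coefficient, > 0.
#' @param deltaAT total anisotropy change, > 0.
#' @return numeric vector of predicted anisotropy changes.
#' @examples
#' hillModel(10, kd = 10, h = 2, deltaAT = 1)  # 0.5 at half-saturation
#' @export
hillModel <- function(E, kd, h, deltaAT) {
    if (kd <= 0 || h <= 0 || deltaAT <= 0)
        stop("kd, h and deltaAT must all be positive")
    if (any(E < 0)) stop("E must be >= 0")
    deltaAT * E^h / (kd^h + E^h)
}

#' Fit the Hill binding model to an anisotropy titration
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt via
#' \code{\link[minpack.lm]{nlsLM}}) of [hillModel()] to titration points.
#' Default initialization: \code{kd} at the concentration whose observed
#' signal is closest to half the maximum, \code{h = 1}, \code{deltaAT} at
#' the maximum observed signal. All parameters are bounded positive. A fit
#' that fails to converge is returned flagged (\code{@converged == FALSE})
#' rather than raising an error, so titration batches can be processed
#' unattended. The fit is deterministic given the points and the
#' initialization.
#'
#' @param points \code{data.frame} with columns \code{E} (total protein
#'   concentration, >= 0) and \code{delta_A} (anisotropy change); at least
#'   5 points, ideally spanning both sides of half-saturation.
#' @param init optional named numeric \code{c(kd=, h=, deltaAT=)} overriding
#'   the default initialization.
#' @param unit concentration unit tag carried into the result (never
#'   converted).
#' @return a [HillFit-class].
#' @examples
#' E <- 10^seq(log10(0.5), log10(250), length.out = 12)
#' pts <- data.frame(E = E, delta_A = hillModel(E, 19, 1, 1))
#' coef(fitHill(pts, unit = "nM"))
#' @export
fitHill <- function(points, init = NULL, unit = "nM") {
    stopifnot(is.data.frame(points),
              all(c("E", "delta_A") %in% names(points)))
    points <- points[c("E", "delta_A")]
    if (nrow(points) < 5L) stop("need at least 5 titration points")
    if (any(points$E < 0)) stop("E must be >= 0")
    if (is.null(init)) {
        maxA <- max(points$delta_A)
        half <- which.min(abs(points$delta_A - maxA / 2))
        init <- c(kd = max(points$E[half], .Machine$double.eps),
                  h = 1, deltaAT = maxA)
    }
    stopifnot(identical(sort(names(init)), c("deltaAT", "h", "kd")))
    fit <- tryCatch(
        minpack.lm::nlsLM(
            delta_A ~ deltaAT * E^h / (kd^h + E^h),
            data = points,
            start = as.list(init[c("kd", "h", "deltaAT")]),
            lower = c(kd = 1e-12, h = 1e-3, deltaAT = 1e-12),
            control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    if (is.null(fit)) {
        pred <- init[["deltaAT"]] * points$E^init[["h"]] /
            (init[["kd"]]^init[["h"]] + points$E^init[["h"]])
        return(new("HillFit",
                   estimates = init[c("kd", "h", "deltaAT")],
                   se = c(kd = NA_real_, h = NA_real_, deltaAT = NA_real_),
                   residualNorm = sum((points$delta_A - pred)^2),
                   converged = FALSE, unit = unit, data = points))
    }
    if (!isTRUE(fit$convInfo$isConv)) {
        est <- stats::coef(fit)[c("kd", "h", "deltaAT")]
        return(new("HillFit", estimates = est,
                   se = c(kd = NA_real_, h = NA_real_, deltaAT = NA_real_),
                   residualNorm = sum(stats::residuals(fit)^2),
                   converged = FALSE, unit = unit, data = points))
    }
    est <- stats::coef(fit)[c("kd", "h", "deltaAT")]
    se <- tryCatch(summary(fit)$coefficients[c("kd", "h", "deltaAT"),
                                             "Std. Error"],
                   error = function(e)
                       c(kd = NA_real_, h = NA_real_, deltaAT = NA_real_))
    names(se) <- c("kd", "h", "deltaAT")
    new("HillFit", estimates = est, se = se,
        residualNorm = sum(stats::residuals(fit)^2),
        converged = TRUE, unit = unit, data = points)
}

#' Simulate an anisotropy titration from the Hill model
#'
#' Evaluates [hillModel()] at the given concentrations and adds i.i.d.
#' Gaussian noise. Useful for fit validation and parameter-recovery
#' studies; seed the RNG outside for reproducibility.
#'
#' @param E concentrations at which to titrate.
#' @param kd,h,deltaAT ground-truth model parameters.
#' @param noiseSd standard deviation of additive Gaussian noise (0 for a
#'   noiseless curve).
#' @return \code{data.frame} with columns \code{E}, \code{delta_A}.
#' @export
simulateTitration <- function(E, kd, h = 1, deltaAT = 1, noiseSd = 0) {
    y <- hillModel(E, kd, h, deltaAT)
    if (noiseSd > 0) y <- y + stats::rnorm(length(E), sd = noiseSd)
    data.frame(E = E, delta_A = y)
}

#' Read and write titration data and fit results
#'
#' \code{readTitration} reads a CSV with columns \code{E} and
#' \code{delta_A}; a comment line \code{# unit: <u>} (or a column named
#' \code{unit}) tags the concentration unit, defaulting to \code{nM}.
#' \code{writeHillFit} serializes a [HillFit-class] as JSON.
#'
#' @param path CSV file (\code{readTitration}) or JSON output path
#'   (\code{writeHillFit}).
#' @return \code{readTitration}: a \code{data.frame} with attribute
#'   \code{unit}; \code{writeHillFit}: invisibly, \code{path}.
#' @export
readTitration <- function(path) {
    lines <- readLines(path)
    unitLn <- grep("^#\\s*unit:", lines, value = TRUE)
    tab <- utils::read.csv(text = lines, comment.char = "#",
                           stringsAsFactors = FALSE)
    if (!all(c("E", "delta_A") %in% names(tab)))
        stop("titration CSV needs columns E and delta_A")
    unit <- if (length(unitLn)) {
        trimws(sub("^#\\s*unit:\\s*", "", unitLn[1]))
    } else if ("unit" %in% names(tab)) {
        tab$unit[1]
    } else "nM"
    tab <- tab[c("E", "delta_A")]
    attr(tab, "unit") <- unit
    tab
}

#' @rdname readTitration
#' @param fit a [HillFit-class].
#' @export
writeHillFit <- function(fit, path) {
    doc <- list(
        estimates = as.list(fit@estimates),
        standard_errors = as.list(fit@se),
        residual_norm = fit@residualNorm,
        converged = fit@converged,
        unit = fit@unit,
        n_points = nrow(fit@data))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
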