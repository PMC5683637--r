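#' @include virtual-species.R
NULL

newOccurrences <- function(x, y, cls, level, row, col, speciesId, seed,
                           draws) {
  out <- data.frame(
    x = x, y = y,
    observedClass = cls,
    precisionLevel = as.integer(level),
    trueRow = as.integer(row), trueCol = as.integer(col)
  )
  attr(out, "speciesId") <- speciesId
  attr(out, "seed") <- seed
  attr(out, "draws") <- draws
  out
}

# rejection sampler over a cell index set with per-cell acceptance
# probabilities; returns accepted cell indices and the number of offers made
acceptReject <- function(cells, prob, n, nOffers, maxDraws) {
  accepted <- integer(0)
  offers <- 0L
  repeat {
    batch <- if (!is.null(nOffers)) nOffers - offers
      else max(1000L, 4L * (n - length(accepted)))
    if (batch <= 0L) break
    idx <- cells[sample.int(length(cells), batch, replace = TRUE)]
    keep <- stats::runif(batch) <= prob[idx]
    if (is.null(nOffers) && length(accepted) + sum(keep) >= n) {
      # count only the offers up to and including the n-th acceptance
      nth <- which(cumsum(keep) == n - length(accepted))[1]
      offers <- offers + nth
      head <- seq_len(nth)
      accepted <- c(accepted, idx[head][keep[head]])
      break
    }
    offers <- offers + batch
    accepted <- c(accepted, idx[keep])
    if (is.null(nOffers) && offers >= maxDraws)
      stop("acceptance sampling stalled after ", offers,
           " offers (suitability too low?)", call. = FALSE)
  }
  list(cells = accepted, offers = offers)
}

samplePoints <- function(species, n, seed, nOffers, maxDraws, presence) {
  tr <- species@trueRange@values
  suit <- species@suitability@values
  region <- which(!is.na(tr) & tr == (if (presence) 1 else 0))
  if (!length(region))
    stop("species has no ", if (presence) "presence" else "absence",
         " cells", call. = FALSE)
  prob <- if (presence) suit else 1 - suit
  spec <- species@suitability@spec
  nr <- spec@nrows
  withSeed(seed, {
    res <- acceptReject(region, as.vector(prob), n, nOffers, maxDraws)
    k <- length(res$cells)
    row <- ((res$cells - 1L) %% nr) + 1L
    col <- ((res$cells - 1L) %/% nr) + 1L
    cs <- spec@cellSize
    x <- spec@originX + (col - 1 + stats::runif(k)) * cs
    y <- spec@originY + (nr - row + stats::runif(k)) * cs
    newOccurrences(
      x, y, if (presence) "presence" else "absence",
      0L, row, col, species@params@label, seed, res$offers
    )
  })
}

#' Sample presence occurrences from a virtual species
#'
#' Draws cells uniformly from the presence region of the binary true range
#' and accepts each offered cell with probability equal to its suitability
#' (one Bernoulli trial per offer: a cell with suitability 0.8 is accepted
#' in 80% of offers), so higher-suitability cells are proportionally more
#' likely to be sampled.  Accepted occurrences are placed uniformly at
#' random within their cell.
#'
#' Two stopping modes: with `n`, sampling continues until exactly `n`
#' occurrences are accepted (capped at `maxDraws` offers); with `nOffers`,
#' exactly `nOffers` offers are made and all accepted occurrences are
#' returned (fixed survey effort), which is the natural mode for
#' calibration checks of the acceptance rule.
#'
#' @param species a [VirtualSpecies-class] with a non-empty presence region
#' @param n number of occurrences to accept (ignored when `nOffers` given)
#' @param seed integer seed; the result is reproducible from it
#' @param nOffers optional fixed number of offers
#' @param maxDraws cap on offers in fixed-`n` mode
#' @return data.frame with columns `x`, `y`, `observedClass`,
#'   `precisionLevel` (0), `trueRow`, `trueCol`, plus attributes
#'   `speciesId`, `seed` and `draws` (total offers made)
#' @examples
#' stack <- generateEnvStack(GridSpec(40, 40), 4, seed = 1)
#' sp <- makeSpecies(stack, "generalist")
#' occ <- samplePresences(sp, n = 20, seed = 7)
#' nrow(occ)
#' @export
samplePresences <- function(species, n = 100, seed = 1, nOffers = NULL,
                            maxDraws = max(100000, 1000 * n)) {
  stopIfNot(is.null(nOffers) || nOffers >= 1, "nOffers must be >= 1")
  stopIfNot(!is.null(nOffers) || n >= 1, "n must be >= 1")
  samplePoints(species, n, seed, nOffers, maxDraws, presence = TRUE)
}

#' Sample true absences from a virtual species
#'
#' Mirror image of [samplePresences()]: cells are drawn uniformly from the
#' absence region of the binary true range and accepted with probability
#' `1 - suitability`, so the least suitable cells are the most likely to
#' yield absences.  All returned points lie outside the binary range.
#'
#' @inheritParams samplePresences
#' @return data.frame as in [samplePresences()], with
#'   `observedClass = "absence"`
#' @export
sampleAbsences <- function(species, n = 100, seed = 1, nOffers = NULL,
                           maxDraws = max(100000, 1000 * n)) {
  stopIfNot(is.null(nOffers) || nOffers >= 1, "nOffers must be >= 1")
  stopIfNot(!is.null(nOffers) || n >= 1, "n must be >= 1")
  samplePoints(species, n, seed, nOffers, maxDraws, presence = FALSE)
}

#' Degrade the positional accuracy of occurrences
#'
#' Injects controlled positional error.  Level 0 returns the points
#' unchanged (precise).  Level `k >= 1` displaces each point in a uniformly
#' random direction by a distance drawn uniformly from the annulus
#' `(k * w, (k + 1) * w]`, where `w` is the cell width — i.e. just outside a
#' buffer of `k` pixels around the true position, mirroring low /
#' intermediate / high imprecision for `k` = 1, 2, 3.  Displaced points
#' falling outside the study extent are re-drawn (direction and distance),
#' avoiding pile-up at the edges.
#'
#' @param occs occurrence data.frame from [samplePresences()] /
#'   [sampleAbsences()]
#' @param level precision level, 0 (precise) to 3 (highly imprecise)
#' @param spec the study-area [GridSpec-class] (defines `w` and the extent)
#' @param seed integer seed
#' @return occurrence data.frame with updated coordinates and
#'   `precisionLevel = level`
#' @export
degradePositions <- function(occs, level, spec, seed = 1) {
  stopIfNot(level %in% 0:3, "level must be one of 0, 1, 2, 3")
  out <- occs
  out$precisionLevel <- as.integer(level)
  if (level == 0L) return(out)
  w <- spec@cellSize
  n <- nrow(occs)
  withSeed(seed, {
    x <- occs$x
    y <- occs$y
    todo <- seq_len(n)
    guard <- 0L
    while (length(todo)) {
      m <- length(todo)
      theta <- stats::runif(m, 0, 2 * pi)
      # distance uniform on (k*w, (k+1)*w]: 1 - runif lies in (0, 1]
      d <- (level + (1 - stats::runif(m))) * w
      nx <- occs$x[todo] + d * cos(theta)
      ny <- occs$y[todo] + d * sin(theta)
      ok <- insideExtent(spec, nx, ny)
      x[todo[ok]] <- nx[ok]
      y[todo[ok]] <- ny[ok]
      todo <- todo[!ok]
      guard <- guard + 1L
      if (guard > 10000L)
        stop("could not place displaced points inside the extent",
             call. = FALSE)
    }
    out$x <- x
    out$y <- y
    out
  })
}

#' Write occurrences as CSV
#'
#' @param occs occurrence data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
writeOccurrences <- function(occs, path) {
  df <- occs
  df$speciesId <- attr(occs, "speciesId")
  df$seed <- attr(occs, "seed")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
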