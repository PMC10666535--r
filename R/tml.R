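# Transformational machine learning: a compound is represented by the
# vector of predictions that per-species first-stage forests make for it;
# per-species second-stage forests then learn on that representation, so a
# low-resource species can lean on the consensus of better-resourced ones.

.fit_tml <- function(table, spec, stacked) {
  species <- sort(unique(table$species))
  first <- list()
  for (i in seq_along(species)) {
    idx <- which(table$species == species[i])
    if (length(idx) < 2L) {
      # cannot grow a forest: excluded from the representation
      message("tml: species ", species[i],
              " has < 2 rows; excluded from first stage")
      next
    }
    first[[species[i]]] <- rf_fit(table$x[idx, , drop = FALSE],
                                  table$y[idx],
                                  ntree = spec$hyper$ntree,
                                  mtry = spec$hyper$mtry,
                                  min_node = spec$hyper$min_node,
                                  seed = .subseed(spec$seed, i))
  }
  if (length(first) == 0L)
    stop("tml: no species with enough rows for a first-stage model")

  second <- list()
  for (sp in species) {
    idx <- which(table$species == sp)
    rep_x <- tml_represent(first, table$x[idx, , drop = FALSE],
                           exclude = if (!spec$hyper$include_self) sp)
    second[[sp]] <- if (length(idx) < 2L)
      list(mean = mean(table$y[idx]))
    else
      rf_fit(rep_x, table$y[idx], ntree = spec$hyper$ntree,
             mtry = spec$hyper$mtry, min_node = spec$hyper$min_node,
             seed = .subseed(spec$seed, 500L + match(sp, species)))
  }
  list(first = first, second = second,
       include_self = spec$hyper$include_self, stacked = stacked)
}

#' Transformational representation of compounds
#'
#' Places the predictions of every first-stage per-species model for the
#' given rows into a vector; the representation dimension equals the
#' number of first-stage models (minus any excluded).
#'
#' @param first_stage named list of fitted first-stage models.
#' @param x feature matrix (chemical features + duration).
#' @param exclude optional species names whose model is left out.
#' @return numeric matrix, one column per retained first-stage model.
#' @export
tml_represent <- function(first_stage, x, exclude = NULL) {
  keep <- setdiff(names(first_stage), exclude)
  if (length(keep) == 0L) stop("tml representation would be empty")
  x <- as.matrix(x)
  out <- matrix(0, nrow(x), length(keep),
                dimnames = list(NULL, paste0("rep_", keep)))
  for (k in seq_along(keep))
    out[, k] <- predict(first_stage[[keep[k]]], x)
  out
}

.predict_tml <- function(m, newdata, stacked) {
  out <- numeric(nrow(newdata$x))
  for (sp in unique(newdata$species)) {
    idx <- which(newdata$species == sp)
    rep_x <- tml_represent(m$first, newdata$x[idx, , drop = FALSE],
                           exclude = if (!m$include_self) sp)
    sec <- m$second[[sp]]
    pred <- if (inherits(sec, "aq_rf")) predict(sec, rep_x) else sec$mean
    if (stacked) {
      fs <- if (!is.null(m$first[[sp]]))
        predict(m$first[[sp]], newdata$x[idx, , drop = FALSE])
      else pred  # species had no first-stage model: nothing to stack with
      pred <- (pred + fs) / 2
    }
    out[idx] <- pred
  }
  out
}
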