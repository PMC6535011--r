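#' Score individuals along the climate-adaptation axis
#'
#' Refits the constrained ordination on the climate-adaptive loci only
#' and extracts each individual's site score on the constrained axis most
#' strongly aligned with the temperature predictor (largest absolute
#' temperature biplot score). The axis is oriented so that the
#' temperature vector points positive, i.e. positive scores = hot-dry
#' multilocus genotypes, negative = cold-wet.
#'
#' @param gm a complete genotype_matrix.
#' @param candidates a `candidate_set` of adaptive loci (>= 2 loci).
#' @param X climate predictors; the temperature variable is named by
#'   `temperature_var`.
#' @param temperature_var column of `X` anchoring the orientation
#'   (default: first column).
#' @return object of class `adaptive_score`: data.frame with id, score,
#'   population; attributes `axis` (index used), `biplot` (oriented
#'   predictor scores) and `model` (the refitted rda_gea).
#' @export
score_individuals <- function(gm, candidates, X,
                              temperature_var = colnames(as.matrix(X))[1]) {
  ids <- unique(candidates$locus_id)
  if (length(ids) < 2)
    stop("need at least two adaptive loci; relax the outlier/FDR ",
         "thresholds to obtain a larger candidate set")
  gma <- subset_genotypes(gm, loci = ids)
  model <- fit_rda(gma, X)
  bp <- model$biplot
  if (!temperature_var %in% rownames(bp))
    stop("'temperature_var' not among predictors")
  axis <- which.max(abs(bp[temperature_var, ]))
  flip <- if (bp[temperature_var, axis] < 0) -1 else 1
  score <- flip * model$site_wa[, axis]
  out <- data.frame(id = gm$sample_ids, score = as.numeric(score),
                    population = gm$populations %||% NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("adaptive_score", "data.frame")
  attr(out, "axis") <- axis
  attr(out, "biplot") <- flip * bp[, axis]
  attr(out, "model") <- model
  out
}

#' Classify individuals into adaptive groups
#'
#' Individuals with a score above `+t` SDs of the score distribution are
#' labelled hot_dry, below `-t` SDs cold_wet, and intermediate otherwise.
#'
#' @param scores an [score_individuals()] result.
#' @param t non-negative band half-width in SD units (default 0.25).
#' @return object of class `group_assignment`: data.frame with id,
#'   score, population, label.
#' @export
classify_individuals <- function(scores, t = 0.25) {
  if (t < 0) stop("'t' must be non-negative")
  s <- scores$score
  cut <- t * stats::sd(s)
  label <- ifelse(s > cut, "hot_dry",
                  ifelse(s < -cut, "cold_wet", "intermediate"))
  out <- data.frame(id = scores$id, score = s,
                    population = scores$population, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_assignment", "data.frame")
  out
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("group_assignment:\n")
  print(table(x$label))
  invisible(x)
}

#' Classify populations from their members' labels
#'
#' A population is hot_dry when the proportion of hot_dry individuals
#' among its non-intermediate members reaches `majority` (cold_wet
#' symmetrically) and mixed otherwise. Populations with fewer than three
#' individuals are flagged low-confidence.
#'
#' @param assignment a [classify_individuals()] result with population
#'   labels.
#' @param majority required majority in (0.5, 1] (default 0.6).
#' @return data.frame with population, n, prop_hot_dry, prop_cold_wet,
#'   prop_intermediate, label, low_confidence.
#' @export
classify_populations <- function(assignment, majority = 0.6) {
  if (majority <= 0.5 || majority > 1)
    stop("'majority' must lie in (0.5, 1]")
  if (all(is.na(assignment$population)))
    stop("population labels required")
  sp <- split(assignment, assignment$population)
  rows <- lapply(names(sp), function(p) {
    d <- sp[[p]]
    n <- nrow(d)
    ph <- mean(d$label == "hot_dry")
    pc <- mean(d$label == "cold_wet")
    pi <- mean(d$label == "intermediate")
    nh <- sum(d$label == "hot_dry"); ncw <- sum(d$label == "cold_wet")
    lab <- if (nh + ncw == 0) "mixed"
           else if (nh / (nh + ncw) >= majority) "hot_dry"
           else if (ncw / (nh + ncw) >= majority) "cold_wet"
           else "mixed"
    data.frame(population = p, n = n, prop_hot_dry = ph,
               prop_cold_wet = pc, prop_intermediate = pi, label = lab,
               low_confidence = n < 3, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write individual and population assignments as CSV
#' @param assignment a group_assignment.
#' @param path output path for the per-individual table.
#' @param pop_path optional path for the per-population table.
#' @param majority majority rule passed to [classify_populations()].
#' @return invisibly, `path`.
#' @export
write_assignments <- function(assignment, path, pop_path = NULL,
                              majority = 0.6) {
  utils::write.csv(as.data.frame(assignment), path, row.names = FALSE)
  if (!is.null(pop_path))
    utils::write.csv(classify_populations(assignment, majority),
                     pop_path, row.names = FALSE)
  invisible(path)
}
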