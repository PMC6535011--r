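#' Individuals-by-loci genotype matrix
#'
#' Diploid genotypes coded as counts 0/1/2 of the minor allele, with `NA`
#' for missing calls, plus sample and locus identifiers, optional
#' population labels, and optional sample coordinates.
#'
#' @param values integer matrix, individuals in rows, loci in columns;
#'   entries in {0, 1, 2, NA}.
#' @param sample_ids,locus_ids unique identifiers.
#' @param populations optional population label per individual.
#' @param coords optional two-column (x, y) matrix of sample locations.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, sample_ids = rownames(values),
                            locus_ids = colnames(values),
                            populations = NULL, coords = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (any(!is.na(values) & !(values %in% 0:2)))
    stop("genotype values must be 0, 1, 2 or NA")
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%03d", seq_len(nrow(values)))
  if (is.null(locus_ids)) locus_ids <- sprintf("locus%05d", seq_len(ncol(values)))
  if (length(sample_ids) != nrow(values) || length(locus_ids) != ncol(values))
    stop("id lengths must match matrix dimensions")
  if (anyDuplicated(locus_ids)) stop("locus ids must be unique")
  if (!is.null(populations) && length(populations) != nrow(values))
    stop("'populations' must have one label per individual")
  dimnames(values) <- list(sample_ids, locus_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 locus_ids = locus_ids, populations = populations,
                 coords = coords),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci", nrow(x$values),
              ncol(x$values)))
  if (!is.null(x$populations))
    cat(sprintf(", %d populations", length(unique(x$populations))))
  cat(sprintf("; genotyping rate %.3f\n", genotyping_rate(x)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Proportion of non-missing genotype calls
#' @param gm a genotype_matrix.
#' @return scalar in [0, 1].
#' @export
genotyping_rate <- function(gm) mean(!is.na(gm$values))

#' Subset a genotype matrix by individuals and/or loci
#' @param gm a genotype_matrix.
#' @param samples,loci index, logical or id vectors; default keep all.
#' @return genotype_matrix.
#' @export
subset_genotypes <- function(gm, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(gm$values)) else samples
  if (is.character(si)) si <- match(si, gm$sample_ids)
  li <- if (is.null(loci)) seq_len(ncol(gm$values)) else loci
  if (is.character(li)) li <- match(li, gm$locus_ids)
  genotype_matrix(gm$values[si, li, drop = FALSE],
                  sample_ids = gm$sample_ids[si],
                  locus_ids = gm$locus_ids[li],
                  populations = gm$populations[si],
                  coords = if (!is.null(gm$coords))
                    gm$coords[si, , drop = FALSE])
}

## per-locus frequency of the counted allele, ignoring missing
counted_allele_freq <- function(gm) {
  colMeans(gm$values, na.rm = TRUE) / 2
}

#' Read a Genepop genotype file
#'
#' Accepts the standard dialect: a title line, locus names (one per line
#' or comma-separated), case-insensitive `Pop` separators, and individual
#' lines `name , genotype genotype ...` with 2- or 3-digit allele codes
#' (`00`/`000` = missing allele). Biallelic loci are recoded to counts of
#' the minor allele (ties counted on the higher-coded allele); loci with
#' more than two alleles are dropped with a warning.
#'
#' @param path file path.
#' @return a [genotype_matrix()] with populations from the Pop blocks.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("Genepop file too short: ", path)
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found in ", path)
  locus_lines <- lines[2:(first_pop - 1)]
  locus_ids <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_ids <- locus_ids[nzchar(locus_ids)]
  L <- length(locus_ids)
  ids <- character(0); pops <- character(0)
  a1 <- list(); a2 <- list()  # allele codes per individual
  pop_no <- 0L
  for (i in seq(first_pop, length(lines))) {
    if (is_pop[i]) { pop_no <- pop_no + 1L; next }
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2)
      stop("line ", i, ": expected 'name , genotypes' in ", path)
    nm <- trimws(parts[1])
    genos <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                      "\\s+")[[1]]
    if (length(genos) != L)
      stop(sprintf("line %d: %d genotypes for %d loci", i,
                   length(genos), L))
    w <- nchar(genos)
    if (any(w != 4 & w != 6))
      stop("line ", i, ": allele codes must be 2 or 3 digits")
    half <- w / 2
    ids <- c(ids, nm)
    pops <- c(pops, sprintf("pop%02d", pop_no))
    a1[[length(a1) + 1L]] <- as.integer(substr(genos, 1, half))
    a2[[length(a2) + 1L]] <- as.integer(substr(genos, half + 1, w))
  }
  A1 <- do.call(rbind, a1); A2 <- do.call(rbind, a2)
  A1[A1 == 0L] <- NA_integer_; A2[A2 == 0L] <- NA_integer_
  n <- nrow(A1)
  counts <- matrix(NA_integer_, n, L)
  keep <- rep(TRUE, L)
  for (l in seq_len(L)) {
    al <- c(A1[, l], A2[, l])
    alleles <- sort(unique(al[!is.na(al)]))
    if (length(alleles) > 2) {
      keep[l] <- FALSE
      next
    }
    if (length(alleles) == 0) next
    ## counted allele: the minor (rarer) one; ties -> higher code
    if (length(alleles) == 1) {
      counted <- alleles[1]
      counts[, l] <- ifelse(is.na(A1[, l]) | is.na(A2[, l]), NA_integer_,
                            2L)
      ## single observed allele: everyone homozygous for it; code as 0
      ## (no minor allele present)
      counts[!is.na(counts[, l]), l] <- 0L
    } else {
      f2 <- mean(al == alleles[2], na.rm = TRUE)
      counted <- if (f2 <= 0.5) alleles[2] else alleles[1]
      counts[, l] <- (A1[, l] == counted) + (A2[, l] == counted)
      counts[is.na(A1[, l]) | is.na(A2[, l]), l] <- NA_integer_
    }
  }
  if (any(!keep)) {
    warning(sum(!keep), " locus/loci with >2 alleles excluded")
    counts <- counts[, keep, drop = FALSE]
    locus_ids <- locus_ids[keep]
  }
  genotype_matrix(counts, sample_ids = make.unique(ids),
                  locus_ids = locus_ids, populations = pops)
}

#' Write a genotype matrix as canonical Genepop
#'
#' Emits 3-digit allele codes: count-0 homozygote `001001`, heterozygote
#' `001002`, count-2 homozygote `002002`, missing `000000`. The file is
#' re-readable by [read_genepop()] with identical counts, missingness and
#' population structure.
#'
#' @param gm a genotype_matrix with population labels.
#' @param path output path.
#' @param title first line of the file.
#' @return invisibly, `path`.
#' @export
write_genepop <- function(gm, path, title = "adaptscape export") {
  if (is.null(gm$populations))
    stop("population labels are required to write Genepop")
  pops <- unique(gm$populations)
  if (any(table(gm$populations) == 0) || length(pops) == 0)
    stop("empty population block")
  code <- c(`0` = "001001", `1` = "001002", `2` = "002002")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(gm$locus_ids, con)
  for (p in pops) {
    writeLines("Pop", con)
    for (i in which(gm$populations == p)) {
      g <- gm$values[i, ]
      s <- ifelse(is.na(g), "000000", code[as.character(g)])
      writeLines(paste0(gm$sample_ids[i], " , ",
                        paste(s, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Filter loci on minor-allele frequency and missingness
#'
#' @param gm a genotype_matrix.
#' @param maf_min minimum minor-allele frequency in [0, 0.5); loci below
#'   it are dropped.
#' @param max_missing maximum tolerated proportion of missing calls.
#' @return filtered genotype_matrix; the number of loci removed by each
#'   rule is attached as attribute `dropped` (named vector maf, missing).
#' @export
filter_loci <- function(gm, maf_min = 0.01, max_missing = 0.2) {
  if (maf_min < 0 || maf_min >= 0.5)
    stop("'maf_min' must lie in [0, 0.5)")
  f <- counted_allele_freq(gm)
  maf <- pmin(f, 1 - f)
  miss <- colMeans(is.na(gm$values))
  fail_maf <- maf < maf_min | is.nan(maf)
  fail_miss <- miss > max_missing
  keep <- !(fail_maf | fail_miss)
  out <- subset_genotypes(gm, loci = which(keep))
  attr(out, "dropped") <- c(maf = sum(fail_maf),
                            missing = sum(fail_miss & !fail_maf))
  out
}

#' Impute missing genotypes with the per-locus modal genotype
#'
#' Standard completion step before ordination-based analyses. Ties among
#' modal genotypes are broken towards the lower count, deterministically.
#'
#' @param gm a genotype_matrix.
#' @return complete genotype_matrix; logical matrix of imputed cells
#'   attached as attribute `imputed`.
#' @export
impute_missing <- function(gm) {
  v <- gm$values
  flagged <- is.na(v)
  for (l in which(colSums(flagged) > 0)) {
    obs <- v[!flagged[, l], l]
    if (length(obs) == 0) { v[, l] <- 0L; next }
    tab <- table(factor(obs, levels = 0:2))
    mode_g <- as.integer(names(tab)[which.max(tab)])  # which.max: first max
    v[flagged[, l], l] <- mode_g
  }
  out <- genotype_matrix(v, sample_ids = gm$sample_ids,
                         locus_ids = gm$locus_ids,
                         populations = gm$populations, coords = gm$coords)
  attr(out, "imputed") <- flagged
  attr(out, "truth") <- attr(gm, "truth")
  out
}

## Weir & Cockerham (1984) per-locus variance components a, b, c for one
## biallelic locus across r populations. x: genotype counts per individual,
## pop: population factor. Returns c(a, b, c) or NA for unusable loci.
wc_components <- function(x, pop) {
  ok <- !is.na(x)
  x <- x[ok]; pop <- factor(pop[ok])
  ni <- tabulate(pop)
  use <- ni >= 1
  if (sum(use) < 2) return(c(NA_real_, NA_real_, NA_real_))
  pop <- factor(pop, levels = levels(pop)[use])
  ni <- ni[use]
  r <- length(ni)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pi <- tapply(x, pop, mean) / 2
  hi <- tapply(x == 1, pop, mean)
  pbar <- sum(ni * pi) / (r * nbar)
  if (pbar <= 0 || pbar >= 1) return(c(0, 0, 0))  # monomorphic overall
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a, b, cc)
}

#' Pairwise Weir & Cockerham FST between populations
#'
#' Computes per-locus variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) following
#' Weir & Cockerham (1984), and the multilocus estimate as the
#' ratio-of-sums theta = sum(a) / sum(a + b + c) for every population
#' pair. Negative estimates are reported as computed. Linearized values
#' theta / (1 - theta) are provided for distance regression, with the
#' denominator clamped at 1e-6.
#'
#' @param gm a genotype_matrix with at least two populations of two or
#'   more genotyped individuals each.
#' @return object of class `fst_matrix`: list with symmetric matrices
#'   `theta` and `linearized` (population x population, zero diagonal)
#'   and the `overall` multilocus estimate across all populations.
#' @export
pairwise_fst <- function(gm) {
  if (is.null(gm$populations)) stop("population labels required")
  pops <- unique(gm$populations)
  if (length(pops) < 2) stop("need at least two populations")
  sizes <- table(gm$populations)
  if (any(sizes < 2)) stop("every population needs >= 2 individuals")
  multilocus <- function(idx) {
    sub_pop <- gm$populations[idx]
    comp <- apply(gm$values[idx, , drop = FALSE], 2, wc_components,
                  pop = sub_pop)
    good <- colSums(is.na(comp)) == 0 & colSums(comp) != 0
    if (!any(good))
      stop("no polymorphic locus available for FST estimation")
    sum(comp[1, good]) / sum(colSums(comp[, good, drop = FALSE]))
  }
  k <- length(pops)
  theta <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    idx <- which(gm$populations %in% pops[c(i, j)])
    theta[i, j] <- theta[j, i] <- multilocus(idx)
  }
  lin <- theta / pmax(1 - theta, 1e-6)
  diag(lin) <- 0
  structure(list(theta = theta, linearized = lin,
                 overall = multilocus(seq_len(nrow(gm$values)))),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat(sprintf("fst_matrix: %d populations, overall theta = %.4f\n",
              nrow(x$theta), x$overall))
  print(round(x$theta, 4))
  invisible(x)
}

#' Write a sample table as CSV
#' @param gm genotype_matrix with coordinates.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sample_table <- function(gm, path) {
  if (is.null(gm$coords)) stop("no coordinates to write")
  utils::write.csv(data.frame(id = gm$sample_ids,
                              lon = gm$coords[, 1], lat = gm$coords[, 2],
                              population = gm$populations %||% NA),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a sample table (id, lon, lat, population) from CSV
#' @param path CSV path.
#' @return data.frame.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("sample table needs columns id, lon, lat")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
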