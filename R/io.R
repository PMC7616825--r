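## Readers and writers for the file formats of the pipeline.

#' Read long-format exposure records
#'
#' CSV with header \code{subject_id,time,value}. Rows with non-numeric or
#' non-finite entries raise an error naming the offending lines. Duplicate
#' (subject, time) rows are kept — repeated measures are allowed — with a
#' message. Times outside an optional domain are dropped with a count.
#'
#' @param path CSV file path.
#' @param domain optional \code{c(0, T)}; out-of-domain records are dropped.
#' @return sorted long-format data frame.
#' @export
readExposure <- function(path, domain = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time", "value")
  if (!all(need %in% names(raw)))
    stop("exposure file must have columns subject_id, time, value")
  for (col in c("time", "value")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric or non-finite '", col, "' at data line(s): ",
           paste(head(bad + 1L, 10L), collapse = ", "))
    raw[[col]] <- v
  }
  if (!is.null(domain)) {
    out <- raw$time < domain[1L] | raw$time > domain[2L]
    if (any(out)) {
      message(sum(out), " record(s) outside the domain dropped")
      raw <- raw[!out, , drop = FALSE]
    }
  }
  dup <- duplicated(raw[c("subject_id", "time")])
  if (any(dup))
    message(sum(dup), " duplicate (subject, time) record(s) kept as repeated measures")
  checkLongData(raw)
}

#' Read a genotype dosage matrix
#'
#' Accepts a CSV (\code{subject_id} column plus one dosage column per
#' variant) or a VCF (detected by file extension). For VCF input the DS
#' (dosage) FORMAT field is used when present, otherwise dosages are
#' alt-allele counts from GT. Missing cells are imputed to the column mean
#' with a message.
#'
#' @param path CSV or VCF path.
#' @return numeric matrix (subjects x variants) with subject row names.
#' @export
readGenotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    return(readGenotypesVcf(path))
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(raw))
    stop("genotype CSV must have a subject_id column")
  ids <- as.character(raw$subject_id)
  G <- as.matrix(raw[setdiff(names(raw), "subject_id")])
  storage.mode(G) <- "double"
  rownames(G) <- ids
  finalizeDosages(G)
}

readGenotypesVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF genotype input requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(ds) && any(is.finite(ds))) {
    G <- t(ds)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    counts <- vapply(as.vector(gt), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(suppressWarnings(as.numeric(strsplit(x, "[/|]")[[1L]])) > 0,
          na.rm = TRUE)
    }, numeric(1L), USE.NAMES = FALSE)
    G <- t(matrix(counts, nrow(gt), ncol(gt),
                  dimnames = dimnames(gt)))
  }
  finalizeDosages(G)
}

finalizeDosages <- function(G) {
  miss <- !is.finite(G)
  if (any(miss)) {
    message(sum(miss), " missing genotype cell(s) imputed to column means")
    for (j in which(colSums(miss) > 0)) {
      mj <- mean(G[!miss[, j], j])
      G[miss[, j], j] <- mj
    }
  }
  if (any(G < 0 | G > 2))
    stop("dosages must lie in [0, 2]")
  zv <- apply(G, 2L, var) == 0
  if (any(zv)) message(sum(zv), " zero-variance variant column(s) flagged")
  attr(G, "zeroVariance") <- colnames(G)[zv]
  G
}

#' Read the outcome vector
#'
#' CSV with columns \code{subject_id} and \code{y}.
#'
#' @param path CSV path.
#' @return named numeric vector.
#' @export
readOutcome <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "y") %in% names(raw)))
    stop("outcome file must have columns subject_id, y")
  y <- suppressWarnings(as.numeric(raw$y))
  if (any(!is.finite(y)))
    stop("non-finite outcome at data line(s): ",
         paste(head(which(!is.finite(y)) + 1L, 10L), collapse = ", "))
  setNames(y, as.character(raw$subject_id))
}

#' Write simulated inputs to a directory
#'
#' Writes \code{exposure.csv}, \code{genotypes.csv}, \code{outcome.csv} and a
#' \code{truth.json} sidecar (scenario labels, true effect curve on the dense
#' grid, master seed) for provenance.
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pe <- file.path(dir, "exposure.csv")
  write.csv(sim$exposure, pe, row.names = FALSE)
  pg <- file.path(dir, "genotypes.csv")
  write.csv(data.frame(subject_id = rownames(sim$genotypes),
                       sim$genotypes, check.names = FALSE),
            pg, row.names = FALSE)
  po <- file.path(dir, "outcome.csv")
  write.csv(data.frame(subject_id = names(sim$outcome), y = sim$outcome),
            po, row.names = FALSE)
  pt <- file.path(dir, "truth.json")
  grid <- sim$alpha$grid
  jsonlite::write_json(list(exposureScenario = sim$cfg$exposureScenario,
                            outcomeScenario = sim$cfg$outcomeScenario,
                            seed = sim$cfg$seed, grid = grid,
                            beta = trueBeta(sim$cfg$outcomeScenario, grid)),
                       pt, auto_unbox = TRUE, digits = NA)
  invisible(c(pe, pg, po, pt))
}

#' Serialise an FPCA model to JSON
#'
#' @param model an \code{\linkS4class{FpcaModel}}.
#' @param path output JSON path; scores are written separately by
#'   \code{\link{writeScores}}.
#' @return invisibly, \code{path}.
#' @export
writeFpcaModel <- function(model, path) {
  jsonlite::write_json(list(grid = model@grid, mu = model@mu,
                            phi = model@phi, lambda = model@lambda,
                            sigma2 = model@sigma2, fve = model@fve),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write PACE scores to CSV
#'
#' @param model an \code{\linkS4class{FpcaModel}}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeScores <- function(model, path) {
  write.csv(data.frame(subject_id = model@subjectIds, model@scores,
                       check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}
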