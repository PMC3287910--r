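# Readers and writers: VCF / TSV genotypes, annotation sidecar, phenotype
# table, per-window results. All genotype input is normalised to minor-allele
# dosages in {0,1,2} with missing values imputed to the rounded per-SNP mean
# and monomorphic SNPs dropped.

#' Genotype matrix container
#'
#' Bundles an integer minor-allele dosage matrix with SNP metadata and
#' individual ids. Entries are 0/1/2 counts of the minor allele; SNPs are
#' genome-sorted (chromosome, then position).
#'
#' @param dosages Integer matrix, individuals x SNPs, entries in `{0,1,2}`.
#' @param snps Tibble with columns `id`, `chromosome`, `position`, `gene`,
#'   `is_nonsynonymous` (and `maf`, filled in if absent).
#' @param individual_ids Character vector, one per row of `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snps, individual_ids) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(snps) == ncol(dosages),
            length(individual_ids) == nrow(dosages))
  if (!all(dosages %in% c(0, 1, 2))) {
    stop("dosages must be minor-allele counts in {0, 1, 2}")
  }
  snps <- as_tibble(snps)
  req <- c("id", "chromosome", "position", "gene", "is_nonsynonymous")
  missing_cols <- setdiff(req, names(snps))
  if (length(missing_cols)) {
    stop("snps table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  ord <- order(snps$chromosome, snps$position)
  snps <- snps[ord, ]
  dosages <- dosages[, ord, drop = FALSE]
  dup <- duplicated(paste(snps$chromosome, snps$position))
  if (any(dup)) {
    warning(sum(dup), " SNP(s) share a chromosome/position")
  }
  dimnames(dosages) <- list(individual_ids, snps$id)
  snps$maf <- compute_maf(dosages)
  structure(list(dosages = dosages, snps = snps,
                 individual_ids = as.character(individual_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d nonsynonymous)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$snps$is_nonsynonymous)))
  cat(sprintf("  MAF range: %.4g - %.4g\n",
              min(x$snps$maf), max(x$snps$maf)))
  invisible(x)
}

# orient a raw allele-count matrix to the minor allele, impute missing
# entries to the rounded per-SNP mean, and drop monomorphic columns
normalize_dosages <- function(d, snps) {
  d <- as.matrix(d)
  for (j in seq_len(ncol(d))) {
    mis <- is.na(d[, j])
    if (all(mis)) {
      d[, j] <- 0 # entirely missing -> monomorphic, dropped below
    } else if (any(mis)) {
      d[mis, j] <- round(mean(d[!mis, j]))
    }
  }
  af <- colMeans(d) / 2
  flip <- af > 0.5
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  mono <- colMeans(d) %in% c(0, 2)
  if (any(mono)) {
    ws_msg("dropping %d monomorphic SNP(s)", sum(mono))
  }
  if (all(mono)) stop("no polymorphic SNPs remain after orientation")
  list(dosages = d[, !mono, drop = FALSE],
       snps = snps[!mono, , drop = FALSE],
       n_dropped = sum(mono), n_flipped = sum(flip))
}

default_annotation <- function(ids, n0 = seq_along(ids)) {
  tibble(id = ids, chromosome = "un", position = as.integer(n0),
         gene = "", is_nonsynonymous = FALSE)
}

join_annotation <- function(ids, annotation) {
  if (is.null(annotation)) return(default_annotation(ids))
  ann <- as_tibble(annotation)
  names(ann)[names(ann) == "snp_id"] <- "id"
  hit <- match(ids, ann$id)
  if (anyNA(hit)) {
    warning(sum(is.na(hit)),
            " SNP id(s) absent from annotation; retained with empty gene")
  }
  out <- default_annotation(ids)
  ok <- !is.na(hit)
  for (col in intersect(c("chromosome", "position", "gene",
                          "is_nonsynonymous"), names(ann))) {
    out[[col]][ok] <- ann[[col]][hit[ok]]
  }
  out$position <- as.integer(out$position)
  out$is_nonsynonymous <- as.logical(out$is_nonsynonymous)
  out
}

#' Read genotypes from a VCF file
#'
#' Parses GT fields of a VCF into a minor-allele dosage matrix. Multiallelic
#' records are skipped, missing genotypes are imputed to the rounded per-SNP
#' mean, columns whose ALT frequency exceeds 0.5 are flipped to count the
#' minor allele, and monomorphic SNPs are dropped.
#'
#' @param path Path to a (plain-text) VCF with GT in FORMAT.
#' @param annotation Optional annotation tibble/data frame
#'   (`snp_id`/`id`, `gene`, `is_nonsynonymous`) joined by SNP id; chromosome
#'   and position always come from the VCF itself.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, annotation = NULL) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("empty input: VCF has no variant records")
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) stop("empty input: VCF has no samples")
  keep <- !grepl(",", fix$ALT %||% "")
  if (sum(keep) == 0) stop("empty input: no biallelic records")
  if (any(!keep)) ws_msg("skipping %d multiallelic record(s)", sum(!keep))
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)[-1]
  fmt <- gt[, 1]
  gt_pos <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  if (anyNA(gt_pos)) {
    stop("malformed VCF: record ", which(is.na(gt_pos))[1],
         " lacks GT in FORMAT")
  }
  body <- gt[, -1, drop = FALSE]
  calls <- matrix(NA_real_, nrow(body), ncol(body))
  for (i in seq_len(nrow(body))) {
    cell <- vapply(strsplit(body[i, ], ":", fixed = TRUE),
                   function(x) x[gt_pos[i]], character(1))
    al <- strsplit(cell, "[/|]")
    calls[i, ] <- vapply(al, function(x) {
      if (length(x) != 2 || any(x == ".")) return(NA_real_)
      xi <- suppressWarnings(as.numeric(x))
      if (anyNA(xi) || any(!xi %in% c(0, 1))) {
        stop("malformed VCF: unparseable GT '", paste(x, collapse = "/"), "'")
      }
      sum(xi)
    }, numeric(1))
  }
  d <- t(calls) # individuals x SNPs
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[noid], ":", fix$POS[noid])
  ann <- join_annotation(ids, annotation)
  ann$chromosome <- fix$CHROM
  ann$position <- as.integer(fix$POS)
  norm <- normalize_dosages(d, ann)
  if (ncol(norm$dosages) == 0) stop("empty input: no SNPs survive filters")
  genotype_matrix(norm$dosages, norm$snps, samples)
}

#' Read genotypes from a tab-separated dosage matrix
#'
#' Expects a header row of SNP ids, a first column of individual ids, and a
#' body of `{0,1,2,NA}` allele counts. The same orientation and imputation
#' contract as [read_vcf()] applies; chromosome, position, gene, and the
#' nonsynonymous flag are joined from the annotation sidecar by SNP id.
#'
#' @param path Path to the TSV.
#' @param annotation Annotation tibble or path to an annotation TSV with
#'   columns `snp_id`, `chromosome`, `position`, `gene`, `is_nonsynonymous`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path, annotation = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0 || ncol(tab) < 2) {
    stop("empty input: genotype TSV has no body")
  }
  ids <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  bad <- !(is.na(d) | d %in% c(0, 1, 2))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid dosage at row %d, column '%s': %s",
                 w[1], colnames(d)[w[2]], d[w[1], w[2]]))
  }
  if (is.character(annotation)) annotation <- read_annotation_tsv(annotation)
  ann <- join_annotation(colnames(d), annotation)
  norm <- normalize_dosages(d, ann)
  if (ncol(norm$dosages) == 0) stop("empty input: no SNPs survive filters")
  genotype_matrix(norm$dosages, norm$snps, ids)
}

#' Read a SNP annotation sidecar
#'
#' @param path TSV with columns `snp_id`, `chromosome`, `position`, `gene`,
#'   `is_nonsynonymous`.
#' @return Tibble.
#' @export
read_annotation_tsv <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ann$is_nonsynonymous <- as.logical(ann$is_nonsynonymous)
  ann
}

#' Read and align a phenotype/covariate table
#'
#' Reads a TSV whose first column holds individual ids, checks that the
#' requested trait and covariate columns are numeric, validates declared
#' binary columns, and reorders rows to the genotype individual order.
#' Individuals present in only one of the two inputs are dropped (counted in
#' a message); no overlap is an error.
#'
#' @param path TSV path, or a data frame already in memory.
#' @param genotypes A [genotype_matrix()] used for alignment, or `NULL` to
#'   skip alignment.
#' @param trait_names,covariate_names Column names that must exist and be
#'   numeric.
#' @param binary_cols Columns that must contain only 0/1.
#' @return Tibble with first column `individual_id`, aligned to the genotype
#'   order, carrying the unmatched-row count in attribute `n_dropped`.
#' @export
read_phenotypes <- function(path, genotypes = NULL,
                            trait_names = NULL, covariate_names = NULL,
                            binary_cols = NULL) {
  tab <- if (is.data.frame(path)) as_tibble(path) else
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0) stop("empty phenotype table")
  names(tab)[1] <- "individual_id"
  tab$individual_id <- as.character(tab$individual_id)
  for (col in c(trait_names, covariate_names)) {
    if (!col %in% names(tab)) stop("phenotype column not found: ", col)
    if (!is.numeric(tab[[col]])) {
      stop("non-numeric values in phenotype column: ", col)
    }
    if (any(!is.finite(tab[[col]]))) {
      stop("missing/non-finite values in phenotype column: ", col)
    }
  }
  for (col in binary_cols) {
    if (!is_binary01(tab[[col]])) {
      stop("binary column '", col, "' contains values outside {0, 1}")
    }
  }
  n_dropped <- 0L
  if (!is.null(genotypes)) {
    hit <- match(genotypes$individual_ids, tab$individual_id)
    if (all(is.na(hit))) {
      stop("no overlapping individuals between genotypes and phenotypes")
    }
    n_dropped <- sum(is.na(hit)) + sum(!tab$individual_id %in%
                                         genotypes$individual_ids)
    if (n_dropped > 0) {
      ws_msg("dropping %d individual(s) present in only one file", n_dropped)
    }
    keep <- which(!is.na(hit))
    tab <- tab[hit[keep], , drop = FALSE]
    # rows of the genotype matrix matching the returned phenotype rows;
    # the pipeline subsets genotypes with this when the overlap is partial
    attr(tab, "genotype_rows") <- keep
  }
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Subset a genotype matrix to a set of individuals
#'
#' Keeps the given rows (in the given order) and re-runs orientation and
#' monomorphic filtering, since allele frequencies change with the cohort.
#'
#' @param g A [genotype_matrix()].
#' @param rows Integer row indices or character individual ids.
#' @return A [genotype_matrix()].
#' @export
subset_individuals <- function(g, rows) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.character(rows)) rows <- match(rows, g$individual_ids)
  if (anyNA(rows)) stop("unknown individual id(s)")
  norm <- normalize_dosages(g$dosages[rows, , drop = FALSE], g$snps)
  genotype_matrix(norm$dosages, norm$snps, g$individual_ids[rows])
}

#' Write per-window association results
#'
#' Tab-separated output in genome order with a `#`-prefixed provenance
#' header (package version, seed, configuration hash). Re-writing identical
#' results produces a byte-identical file.
#'
#' @param results A `ws_result` tibble from [ws_run()] (or any tibble with
#'   the same columns).
#' @param path Output path.
#' @param provenance Optional named list serialised into the header.
#' @return Invisibly, the path.
#' @export
write_results <- function(results, path, provenance = NULL) {
  if (is.null(results) || nrow(results) == 0) stop("no results to write")
  prov <- provenance %||% attr(results, "provenance") %||% list()
  cfg_lines <- vapply(names(prov), function(k)
    sprintf("# %s=%s", k, paste(format(prov[[k]], digits = 15),
                                collapse = ",")),
    character(1))
  header <- c(
    sprintf("# wavescore %s",
            as.character(utils::packageVersion("wavescore"))),
    cfg_lines,
    sprintf("# config_hash=%s",
            ws_hash(if (length(cfg_lines)) cfg_lines else "default"))
  )
  out <- as.data.frame(results[, !vapply(results, is.list, logical(1)),
                               drop = FALSE])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(names(out), collapse = "\t"), con)
  body <- apply(out, 1, function(r)
    paste(trimws(format(r, digits = 15, scientific = FALSE)),
          collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Write a genotype matrix, annotation, and phenotypes as TSV
#'
#' Companions to the readers, used by the cohort simulator's command-line
#' interface and for round-trip testing.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_genotype_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- as_tibble(g$dosages)
  tab <- dplyr::bind_cols(tibble(individual_id = g$individual_ids), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
write_annotation_tsv <- function(g, path) {
  ann <- g$snps[, c("id", "chromosome", "position", "gene",
                    "is_nonsynonymous")]
  names(ann)[1] <- "snp_id"
  readr::write_tsv(ann, path, progress = FALSE)
  invisible(path)
}
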