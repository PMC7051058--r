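# Readers and writers for the formats the pipeline speaks: biallelic VCF
# (GT and/or DS), dosage matrix TSV, variant metadata TSV and phenotype TSV.
# Conventions: VCF coordinates 1-based; dosage = counted (ALT) allele;
# DS takes precedence over GT; "./." (or absent DS) marks a missing call.

.parseGtDosage <- function(gt) {
  # "0/0", "0|1", "1/1", "./." (and haploid "0"/"1") -> dosage or NA
  out <- rep(NA_real_, length(gt))
  known <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
             "1|0" = 1, "1/1" = 2, "1|1" = 2, "0" = 0, "1" = 1)
  idx <- match(gt, names(known))
  out[!is.na(idx)] <- known[idx[!is.na(idx)]]
  rest <- which(is.na(idx) & !is.na(gt) & gt != "./." & gt != ".|." &
                  gt != ".")
  for (i in rest) {
    al <- strsplit(gt[i], "[/|]")[[1]]
    if (any(al == ".")) next
    out[i] <- sum(as.numeric(al))
  }
  out
}

#' Read genotypes into a GwisExperiment
#'
#' Reads a biallelic VCF (via `VariantAnnotation::readVcf`) or a dosage
#' TSV. For VCF, the per-sample dosage is the `DS` field where present and
#' non-missing, else the `GT` allele sum; `"./."` (or an absent `DS`)
#' gives a missing call. Multiallelic records are skipped with a warning.
#' The per-variant imputation quality is taken from the first INFO key
#' among `infoKeys` that is present. For the TSV layout, `path` is the
#' samples x variants dosage table written by [writeCohort()] (first
#' column `sample_id`, one column per variant, empty cells missing) and
#' variant metadata is read from the sibling `*_variants.tsv` when
#' present.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @param infoKeys candidate INFO field names for the imputation quality
#'   score, tried in order.
#' @return a [GwisExperiment-class] (no phenotypes; see
#'   [attachPhenotypes()]).
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "dosage"),
                          infoKeys = c("INFO", "R2")) {
  format <- match.arg(format)
  if (!file.exists(path)) .configError(paste("genotype file not found:",
                                             path))
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") .readGenotypesVcf(path, infoKeys)
  else .readGenotypesDosage(path)
}

.readGenotypesVcf <- function(path, infoKeys) {
  vcf <- readVcf(path, genome = "unknown")
  multi <- lengths(alt(vcf)) > 1L
  if (any(multi))
    warning("skipped ", sum(multi), " multiallelic record(s)")
  vcf <- vcf[!multi, ]
  gen <- geno(vcf)
  d <- NULL
  if ("GT" %in% names(gen)) {
    gt <- gen$GT
    d <- matrix(.parseGtDosage(as.vector(gt)), nrow = nrow(gt),
                dimnames = dimnames(gt))
  }
  if ("DS" %in% names(gen)) {
    ds <- gen$DS
    storage.mode(ds) <- "double"
    if (is.null(d)) d <- ds
    else d[!is.na(ds)] <- ds[!is.na(ds)]  # DS takes precedence
  }
  if (is.null(d)) .dataError("VCF carries neither GT nor DS")
  rr <- rowRanges(vcf)
  infoScore <- rep(NA_real_, nrow(d))
  it <- info(vcf)
  for (k in infoKeys) if (k %in% colnames(it)) {
    v <- it[[k]]
    if (is.list(v) || is(v, "List")) v <- vapply(v, function(e)
      if (length(e)) as.numeric(e[1]) else NA_real_, numeric(1))
    infoScore <- as.numeric(v)
    break
  }
  variants <- DataFrame(
    id = rownames(d),
    chrom = as.character(seqnames(rr)),
    pos = start(rr),
    major = as.character(ref(vcf)),
    minor = as.character(unlist(alt(vcf))),
    info = infoScore)
  GwisExperiment(d, variants = variants)
}

.readGenotypesDosage <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (names(tab)[1] != "sample_id")
    .dataError("dosage TSV must start with a 'sample_id' column")
  d <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(d) <- tab$sample_id
  storage.mode(d) <- "double"
  metaPath <- sub("_dosages\\.tsv$", "_variants.tsv", path)
  variants <- NULL
  if (metaPath != path && file.exists(metaPath)) {
    vt <- read.delim(metaPath, stringsAsFactors = FALSE,
                     comment.char = "#")
    if (nrow(vt) == nrow(d)) variants <- DataFrame(vt)
  }
  GwisExperiment(d, variants = variants)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated, one row per sample; requires `sample_id`, `outcome`
#' (0/1) and `age`; `sex`, `bmi`, `study` and further covariates are
#' carried through.
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) .configError(paste("phenotype file not found:",
                                             path))
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "outcome", "age")
  if (!all(need %in% names(tab)))
    .dataError("phenotype TSV needs columns sample_id, outcome, age")
  if (!all(tab$outcome %in% c(0, 1)))
    .dataError("outcome must be coded 0/1")
  tab
}

#' Attach phenotypes to a GwisExperiment
#'
#' Matches `pheno$sample_id` against the experiment's sample names and
#' installs the phenotype columns as `colData`.
#'
#' @param x a [GwisExperiment-class].
#' @param pheno `data.frame` as from [readPhenotypes()].
#' @return the experiment with phenotypes attached.
#' @export
attachPhenotypes <- function(x, pheno) {
  stopifnot(is(x, "GwisExperiment"))
  i <- match(colnames(x), pheno$sample_id)
  if (any(is.na(i)))
    .dataError(paste("phenotypes missing for", sum(is.na(i)), "sample(s)"))
  cd <- DataFrame(pheno[i, , drop = FALSE])
  rownames(cd) <- colnames(x)
  colData(x) <- cd
  x
}

.stamp <- function(seed, hash) {
  sprintf("# ageGWIS seed=%s config=%s", seed, hash)
}

.writeTsv <- function(tab, path, stamp = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(stamp, con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a cohort to VCF, dosage TSV and phenotype TSV
#'
#' Emits `<prefix>.vcf` (biallelic sites; GT from dosage rounded to the
#' nearest hard call, DS carrying the dosage verbatim, R2 INFO field from
#' `rowData(x)$info`), `<prefix>_dosages.tsv` (samples x variants),
#' `<prefix>_variants.tsv` and `<prefix>_phenotypes.tsv`.
#'
#' @param x a [GwisExperiment-class] with phenotypes in `colData()`.
#' @param prefix output path prefix.
#' @return invisibly, the named vector of file paths written.
#' @export
writeCohort <- function(x, prefix) {
  stopifnot(is(x, "GwisExperiment"))
  d <- dosages(x)
  rd <- rowData(x)
  cd <- as.data.frame(colData(x))
  paths <- c(vcf = paste0(prefix, ".vcf"),
             dosages = paste0(prefix, "_dosages.tsv"),
             variants = paste0(prefix, "_variants.tsv"),
             phenotypes = paste0(prefix, "_phenotypes.tsv"))

  chrom <- if ("chrom" %in% colnames(rd)) rd$chrom else "1"
  pos <- if ("pos" %in% colnames(rd)) rd$pos else seq_len(nrow(d))
  major <- if ("major" %in% colnames(rd)) rd$major else "A"
  minor <- if ("minor" %in% colnames(rd)) rd$minor else "G"
  infoS <- if ("info" %in% colnames(rd))
    sprintf("R2=%g", rd$info) else "."

  con <- file(paths["vcf"], "w")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ageGWIS",
    paste0("##INFO=<ID=R2,Number=1,Type=Float,",
           "Description=\"Imputation quality\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
           "Description=\"Counted allele dosage\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(d)), collapse = "\t")), con)
  gtCode <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(d))) {
    dj <- d[j, ]
    hard <- pmin(pmax(round(dj), 0), 2)
    cell <- ifelse(is.na(dj), "./.:.",
                   paste0(gtCode[hard + 1], ":",
                          formatC(dj, format = "g")))
    writeLines(paste(c(chrom[j], pos[j], rd$id[j], major[j], minor[j],
                       ".", "PASS", infoS[j], "GT:DS", cell),
                     collapse = "\t"), con)
  }
  close(con)

  dos <- data.frame(sample_id = colnames(d),
                    t(d), check.names = FALSE,
                    stringsAsFactors = FALSE)
  .writeTsv(dos, paths["dosages"])
  .writeTsv(as.data.frame(rd), paths["variants"])
  keep <- intersect(c("sample_id", "outcome", "age", "sex", "bmi",
                      "study"), colnames(cd))
  .writeTsv(cd[, keep, drop = FALSE], paths["phenotypes"])
  invisible(paths)
}
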