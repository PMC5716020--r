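## Packaged fixtures: the published Mogou HVS-I haplotype table (55 ancient
## samples, haplotypes ht1-ht46) and the Y-SNP genotype panel of the six
## replicated Mogou males. Grave assignments are synthetic: carriers of a
## shared haplotype are placed in a common grave, which is the sharing
## structure the source data describe (burial-wise haplotype sharing).

.FIXTURE_MD5 <- c(mogou_hvs1_haplotypes.tsv = "307784d03ba290c24c2a2a6488e3134b",
                  mogou_y_snps.tsv = "5d22307982d59d585050c06d97ffb490")

.fixturePath <- function(name) {
  f <- system.file("extdata", name, package = "paleomito")
  if (f == "") stop("fixture ", name, " not found", call. = FALSE)
  got <- unname(tools::md5sum(f))
  if (!is.na(.FIXTURE_MD5[name]) && got != .FIXTURE_MD5[name])
    stop("fixture integrity error: checksum mismatch for ", name,
         call. = FALSE)
  f
}

#' Read a delimited sample table
#'
#' Expects tab-separated columns sample_id, population, grave_id, age_bp,
#' sex, hvs1_motif, coding_snps, haplotype_id, haplogroup. Empty grave_id is
#' treated as unknown, empty haplotype_id/haplogroup as unassigned.
#'
#' @param file path to a TSV file.
#' @return A \linkS4class{PopulationDataset}.
#' @export
readSampleTable <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "population", "grave_id", "age_bp", "sex",
            "hvs1_motif", "coding_snps", "haplotype_id", "haplogroup")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("sample table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d$age_bp <- as.integer(d$age_bp)
  d$sex[is.na(d$sex) | d$sex == ""] <- "unknown"
  d$grave_id[is.na(d$grave_id)] <- ""
  d$haplotype_id[is.na(d$haplotype_id)] <- ""
  d$haplogroup[is.na(d$haplogroup)] <- ""
  motifs <- lapply(seq_len(nrow(d)), function(i)
    mergeMotifs(parseMotif(d$hvs1_motif[i]),
                parseCodingSnps(d$coding_snps[i])))
  names(motifs) <- d$sample_id
  pops <- tapply(d$age_bp, d$population, function(a) a[1])
  new("PopulationDataset",
      samples = d[, c("sample_id", "population", "grave_id", "age_bp",
                      "sex", "haplotype_id", "haplogroup")],
      motifs = motifs,
      populations = setNames(as.numeric(pops), names(pops)))
}

#' Write a PopulationDataset as a delimited sample table
#'
#' @param dataset a \linkS4class{PopulationDataset}.
#' @param file output path.
#' @return The file path, invisibly.
#' @export
writeSampleTable <- function(dataset, file) {
  s <- dataset@samples
  s$hvs1_motif <- vapply(s$sample_id, function(id)
    formatMotif(dataset@motifs[[id]]), character(1))
  s$coding_snps <- vapply(s$sample_id, function(id) {
    m <- dataset@motifs[[id]]
    v <- m@coding
    toks <- vapply(seq_len(nrow(v)), function(i)
      paste0(v$pos[i], if (!is.na(v$base[i])) v$base[i] else ""),
      character(1))
    paste(c(toks, m@markers), collapse = ";")
  }, character(1))
  s <- s[, c("sample_id", "population", "grave_id", "age_bp", "sex",
             "hvs1_motif", "coding_snps", "haplotype_id", "haplogroup")]
  write.table(s, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Load the Mogou HVS-I haplotype fixture
#'
#' The published table of 55 ancient Mogou (~4000 yr BP) samples: HVS-I
#' motifs in 16000+X shorthand, diagnostic coding-region SNPs, haplotype IDs
#' ht1-ht46 and haplogroup labels. Rows that continued a printed motif under
#' a new haplotype ID (e.g. ht15 under ht14) are distinct haplotypes sharing
#' the motif; the haplotype ID is the distinguishing token.
#'
#' @return A \linkS4class{PopulationDataset} with 55 samples.
#' @export
loadMogouHaplotypes <- function() {
  readSampleTable(.fixturePath("mogou_hvs1_haplotypes.tsv"))
}

#' Load the Mogou Y-SNP genotype fixture
#'
#' Genotypes of 6 Mogou males at the 9 markers M216, M89, M9, M214, M231,
#' M175, M122, M324 and P201.
#'
#' @return data.frame with one row per male, one column per marker
#'   (sample_id as row names).
#' @export
loadMogouYGenotypes <- function() {
  d <- read.delim(.fixturePath("mogou_y_snps.tsv"),
                  stringsAsFactors = FALSE, colClasses = "character")
  rownames(d) <- d$sample_id
  d$sample_id <- NULL
  d
}

setMethod("show", "PopulationDataset", function(object) {
  cat("PopulationDataset:", nrow(object@samples), "sample(s) in",
      length(object@populations), "population(s)\n")
  for (p in names(object@populations))
    cat("  ", p, ": n=", sum(object@samples$population == p),
        ", age=", object@populations[[p]], " yr BP\n", sep = "")
})

#' Samples table of a dataset
#' @param x a \linkS4class{PopulationDataset}.
#' @return data.frame of sample annotations.
#' @export
datasetSamples <- function(x) x@samples

#' Motif of one sample
#' @param x a \linkS4class{PopulationDataset}.
#' @param id sample id.
#' @return A \linkS4class{HapMotif}.
#' @export
datasetMotif <- function(x, id) {
  m <- x@motifs[[id]]
  if (is.null(m)) stop("unknown sample id: ", id, call. = FALSE)
  m
}

#' Population sampling ages
#' @param x a \linkS4class{PopulationDataset}.
#' @return Named numeric vector (yr BP).
#' @export
datasetPopulations <- function(x) x@populations
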