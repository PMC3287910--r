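# Small plain-text fixtures generated at test time.

write_test_vcf <- function(path,
                           records = NULL,
                           samples = c("S1", "S2", "S3", "S4")) {
  if (is.null(records)) {
    records <- c(
      # ALT freq 0.5: dosages 0,1,2,1
      "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/1",
      # all ALT: monomorphic after minor-allele orientation -> dropped
      "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t1/1\t1/1\t1/1",
      # missing genotype imputed to round(mean(0,0,1)) = 0
      "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t./.\t0/1",
      # second chromosome, phased separators
      "2\t150\trs4\tT\tC\t.\tPASS\t.\tGT\t0|1\t0|0\t0|1\t0|0"
    )
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

small_genotypes <- function(seed = 42, n = 60, n_genes = 6, spg = 8) {
  simulate_cohort(cohort_spec(n_individuals = n, n_genes = n_genes,
                              snps_per_gene = spg,
                              maf_range = c(0.02, 0.2), seed = seed))
}
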