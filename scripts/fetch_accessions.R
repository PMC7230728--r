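#!/usr/bin/env Rscript
# Downloads the deposited HF1-group isolate genomes from NCBI into the local
# cache consulted by the accession-replay acceptance test and by
# halomotif::replay_isolates(). Requires network access; the package itself
# never fetches anything.
#
#   Rscript scripts/fetch_accessions.R [--dir <path>]

suppressPackageStartupMessages(library(halomotif))

args <- commandArgs(trailingOnly = TRUE)
dir <- file.path(tools::R_user_dir("halomotif", "cache"), "accessions")
if (length(args) >= 2L && args[1L] == "--dir") dir <- args[2L]
dir.create(dir, showWarnings = FALSE, recursive = TRUE)

accessions <- c("AY190604.2",   # HF1
                "AF222060.2",   # HF2
                "MN901520",     # Hardycor2
                "MN901521",     # Serpecor1
                "KC292022.1",   # HRTV-5
                "KC292020.1",   # HRTV-8
                "KC292021.1")   # HRTV-7

efetch <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                 "efetch.fcgi?db=nuccore&id=%s&rettype=%s&retmode=text")

for (acc in accessions) {
  fa <- file.path(dir, paste0(acc, ".fasta"))
  if (!file.exists(fa)) {
    message("fetching ", acc, " (FASTA)")
    utils::download.file(sprintf(efetch, acc, "fasta"), fa, quiet = TRUE)
    Sys.sleep(0.5)  # NCBI rate limit
  }
}
# annotated records (CDS translations) for the CxxC census
for (acc in c("MN901521", "MN901520")) {
  gb <- file.path(dir, paste0(acc, ".gbk"))
  if (!file.exists(gb)) {
    message("fetching ", acc, " (GenBank)")
    utils::download.file(sprintf(efetch, acc, "gbwithparts"), gb,
                         quiet = TRUE)
    Sys.sleep(0.5)
  }
}
message("accession cache ready: ", dir)
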