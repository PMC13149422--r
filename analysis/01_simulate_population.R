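#!/usr/bin/env Rscript
# Simulate the synthetic study population: a toy reference genome with gene
# annotation, 60 accessions carrying one planted causal insertion plus
# neutral background insertions and private SNPs, and GBS-like reads.
# Writes the reference, the carriage truth table, and a read summary.

suppressMessages(library(phosgwas))
dir.create("results", showWarnings = FALSE)

seed <- 42
ref <- generate_reference(n_contigs = 1, contig_length = 60000,
                          n_genes = 10, gene_length = 1500, seed = seed)
write_reference(ref, "results/01_reference.fa", "results/01_reference.gff3")
cat(sprintf("reference: %d bp, %d genes\n",
            nchar(ref$contigs[[1]]$sequence), nrow(ref$genes)))

# plant the causal insertion inside gene 5 at frequency 0.3
g <- ref$genes[5, ]
causal <- data.frame(contig = g$contig, pos = as.integer((g$start + g$end) / 2),
                     ins_len = 31L, freq = 0.3, beta = 1.5)
pop <- simulate_population(ref, n_accessions = 60, causal,
                           n_neutral = 20, snp_rate = 1e-4, seed = seed + 1)
write.table(data.frame(accession_id = rownames(pop$carriage), pop$carriage,
                       check.names = FALSE),
            "results/01_truth_carriage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("population: %d accessions, causal carriers: %d (freq %.2f)\n",
            nrow(pop$truth), sum(pop$truth[, 1]), mean(pop$truth[, 1])))

# one example accession's reads, written as FASTQ
reads <- simulate_gbs_reads(pop$haplotypes[[1]][[1]], read_length = 100,
                            coverage = 30, error = 0, seed = seed + 2)
write_fastq(reads[1:500], "results/01_example_reads.fastq", "acc001")
cat(sprintf("reads per accession at 30x: %d (first 500 written)\n",
            length(reads)))
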