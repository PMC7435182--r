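# Fixtures are built in code at test time; no binary data on disk.

# Three biallelic SNVs with AD fields for two bulk samples, plus an
# optional multiallelic record.
writeToyVcf <- function(file, multiallelic = FALSE) {
    lines <- c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=A01,length=30000000>",
        "##contig=<ID=A02,length=30000000>",
        paste0('##FORMAT=<ID=GT,Number=1,Type=String,',
               'Description="Genotype">'),
        paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,',
               'Description="Allelic depths">'),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tMUT\tWT",
        "A01\t100\t.\tC\tT\t.\t.\t.\tGT:AD\t1/1:0,10\t0/1:5,5",
        "A01\t250\t.\tG\tA\t.\t.\t.\tGT:AD\t0/1:3,7\t0/1:6,4",
        "A02\t80\t.\tT\tC\t.\t.\t.\tGT:AD\t0/1:8,8\t0/1:9,2")
    if (multiallelic)
        lines <- c(lines,
            "A02\t500\t.\tA\tC,G\t.\t.\t.\tGT:AD\t1/2:1,2,3\t0/1:2,2,2")
    writeLines(lines, file)
    file
}

# The same three SNVs in the tabular schema.
writeToyVariantTable <- function(file, sep = "\t") {
    hdr <- paste(c("chrom", "pos", "ref", "alt", "mut_ref", "mut_alt",
                   "wt_ref", "wt_alt"), collapse = sep)
    rows <- c(paste(c("A01", 100, "C", "T", 0, 10, 5, 5), collapse = sep),
              paste(c("A01", 250, "G", "A", 3, 7, 6, 4), collapse = sep),
              paste(c("A02", 80, "T", "C", 8, 8, 9, 2), collapse = sep))
    writeLines(c(hdr, rows), file)
    file
}

# One plus-strand gene with two CDS segments (200 + 301 = 501 bp, in
# frame) on A01:1000-2000.
writeToyGff3 <- function(file, strand = "+") {
    writeLines(c(
        "##gff-version 3",
        paste("A01", "test", "gene", 1000, 2000, ".", strand, ".",
              "ID=g1", sep = "\t"),
        paste("A01", "test", "mRNA", 1000, 2000, ".", strand, ".",
              "ID=g1.t1;Parent=g1", sep = "\t"),
        paste("A01", "test", "CDS", 1000, 1199, ".", strand, "0",
              "ID=g1.t1.cds1;Parent=g1.t1", sep = "\t"),
        paste("A01", "test", "CDS", 1700, 2000, ".", strand, "0",
              "ID=g1.t1.cds2;Parent=g1.t1", sep = "\t")), file)
    file
}

# BED12 encoding of the same gene: exons = CDS segments, thick = CDS span.
writeToyBed12 <- function(file, strand = "+") {
    writeLines(paste("A01", 999, 2000, "g1", 0, strand, 999, 2000, 0, 2,
                     "200,301", "0,700", sep = "\t"), file)
    file
}

# Marker-table text in the layout readMarkerTable() expects.
writeToyMarkerTable <- function(file, calls, chrom, pos, sep = "\t") {
    hdr <- c(paste(c("id", colnames(calls)), collapse = sep),
             paste(c("chrom", chrom), collapse = sep),
             paste(c("pos", pos), collapse = sep))
    rows <- vapply(seq_len(nrow(calls)), function(i)
        paste(c(rownames(calls)[i], calls[i, ]), collapse = sep),
        character(1L))
    writeLines(c(hdr, rows), file)
    file
}

# Exact two-locus F2 genotype-frequency oracle by gamete enumeration.
# Gametes (causal allele, marker allele) have frequencies
# parental (1-r)/2, recombinant r/2; an F2 joins two independent gametes.
# Returns P(marker genotype | recessive homozygote at the causal locus)
# for genotypes B/H/A (0, 1, 2 mutant-parent marker alleles).
twoLocusMarkerFreqOracle <- function(r) {
    gam <- expand.grid(causal = 0:1, marker = 0:1)
    gam$p <- ifelse(gam$causal == gam$marker, (1 - r) / 2, r / 2)
    joint <- numeric(3)   # index = marker allele count + 1
    for (i in seq_len(nrow(gam)))
        for (j in seq_len(nrow(gam))) {
            if (gam$causal[i] == 1 && gam$causal[j] == 1) {
                k <- gam$marker[i] + gam$marker[j] + 1
                joint[k] <- joint[k] + gam$p[i] * gam$p[j]
            }
        }
    joint / sum(joint)
}

# Haldane map: cM distance -> recombination fraction (the simulator's
# no-interference crossover process).
haldaneR <- function(dCM) (1 - exp(-2 * dCM / 100)) / 2

# Does any called region contain the causal locus?
regionContains <- function(regions, chrom, bp) {
    any(as.character(GenomicRanges::seqnames(regions)) == chrom &
        GenomicRanges::start(regions) <= bp &
        GenomicRanges::end(regions) >= bp)
}

# Null PooledVariants: both pools sample the same 0.5 allele frequency.
makeNullVariants <- function(nPerChrom = 2000, nChrom = 3, lenBp = 3e7,
                             depth = 20) {
    n <- nPerChrom * nChrom
    pos <- unlist(lapply(seq_len(nChrom), function(i)
        sort(sample.int(lenBp, nPerChrom))))
    dM <- rpois(n, depth)
    dW <- rpois(n, depth)
    aM <- rbinom(n, dM, 0.5)
    aW <- rbinom(n, dW, 0.5)
    PooledVariants(rep(paste0("chr", seq_len(nChrom)), each = nPerChrom),
                   pos, rep("C", n), rep("T", n),
                   dM - aM, aM, dW - aW, aW)
}
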