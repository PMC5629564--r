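# Programmatic fixture builders (alignment files are written at test time;
# nothing binary is stored in the repository).

write_sam <- function(reads, path = tempfile(fileext = ".sam"),
                      sq = "chr1", ln = 10000L) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", sq, "\tLN:", ln))
  body <- vapply(reads, function(r) {
    paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, "*", 0, 0,
          strrep("A", 40), "*", sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

read_rec <- function(qname, pos, cigar = "40M", flag = 0L, rname = "chr1",
                     mapq = 60L) {
  list(qname = qname, flag = flag, rname = rname, pos = pos, mapq = mapq,
       cigar = cigar)
}

# two-gene GTF identical in layout to the packaged fixture
write_toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  writeLines(c(
    "chr1\ttoy\texon\t1001\t1200\t.\t+\t.\tgene_id \"geneA\";",
    "chr1\ttoy\texon\t1501\t1700\t.\t+\t.\tgene_id \"geneA\";",
    "chr1\ttoy\texon\t1651\t1900\t.\t+\t.\tgene_id \"geneB\";"), path)
  path
}

# small two-group dataset with one strongly changed gene (gene1 up in group b)
toy_de_data <- function(seed = 11, fold = 10) {
  with_seed(seed, {
    ng <- 5
    mu <- c(100, 80, 120, 60, 150)
    X <- matrix(rpois(ng * 6, mu), ng)
    X[1, 4:6] <- rpois(3, mu[1] * fold)
    B <- matrix(rpois(ng * 6, 3), ng)
    rownames(X) <- rownames(B) <- paste0("g", 1:ng)
    list(X = X, B = B, groups = rep(c("a", "b"), each = 3))
  })
}
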