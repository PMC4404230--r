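# internal helpers shared across modules

# Sort rank for chromosome labels: numeric chromosomes first in numeric
# order, then X, then Y, then anything else alphabetically.
chrom_rank <- function(chrom) {
  cc <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  rank <- suppressWarnings(as.numeric(cc))
  rank[is.na(rank) & toupper(cc) == "X"] <- 1e6
  rank[is.na(rank) & toupper(cc) == "Y"] <- 1e6 + 1
  other <- is.na(rank)
  if (any(other)) {
    rank[other] <- 1e6 + 2 + match(cc[other], sort(unique(cc[other])))
  }
  rank
}

is_sex_chrom <- function(chrom) {
  toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE)) %in% c("X", "Y")
}

# GRanges from a data.frame with chromosome/start_bp/end_bp columns
# (1-based inclusive coordinates throughout the package).
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chromosome),
    ranges = IRanges::IRanges(start = df$start_bp, end = df$end_bp)
  )
}

# findOverlaps without the Seqinfo chatter when the two sets happen to
# share no chromosome
overlaps <- function(a, b) {
  suppressWarnings(GenomicRanges::findOverlaps(intervals_to_granges(a),
                                               intervals_to_granges(b)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(msg, class) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
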