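# Independent oracles, deliberately written without reference to the
# package internals they check.

# All-pairs brute-force resolvability: a cluster survives iff no other
# cluster is within r_hard and no same-tag cluster within r_soft
# (closed comparisons; min-image distances under periodic boundaries).
brute_classify <- function(field, rules, geometry = field$geometry) {
  n <- length(field$x)
  if (n == 0L) return(logical(0))
  dx <- abs(outer(field$x, field$x, "-"))
  dy <- abs(outer(field$y, field$y, "-"))
  if (geometry$boundary_mode == "periodic") {
    dx <- pmin(dx, geometry$width_px - dx)
    dy <- pmin(dy, geometry$height_px - dy)
  }
  d2 <- dx^2 + dy^2
  diag(d2) <- Inf
  tag <- field$tag_index
  same <- !is.na(tag) & outer(tag, tag, "==")
  diag(same) <- FALSE
  hard <- apply(d2 <= rules$r_hard^2, 1L, any)
  soft <- apply(d2 <= rules$r_soft^2 & same, 1L, any)
  !(hard | soft)
}

# Textbook one-way fixed-effects ANOVA from sums of squares.
anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  lv <- unique(groups)
  ss_between <- sum(vapply(lv, function(g) {
    y <- values[groups == g]
    length(y) * (mean(y) - gm)^2
  }, numeric(1)))
  ss_within <- sum(vapply(lv, function(g) {
    y <- values[groups == g]
    sum((y - mean(y))^2)
  }, numeric(1)))
  df1 <- length(lv) - 1L
  df2 <- length(values) - length(lv)
  F <- (ss_between / df1) / (ss_within / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# A small read set with exact per-tag counts: each read is its barcode
# followed by a fixed template, constant quality.
exact_tag_reads <- function(tags, per_tag = 100L, read_length = 40L, q_char = "I") {
  bases <- unlist(lapply(tags, function(tg) {
    template <- paste(rep("A", read_length - nchar(tg)), collapse = "")
    rep(paste0(tg, template), per_tag)
  }))
  n <- length(bases)
  read_set(sprintf("r%04d", seq_len(n)), bases,
           strrep(q_char, read_length), offset = 33L)
}

# Hash every file (path + content) under a directory, order-independent.
tree_digest <- function(root) {
  files <- sort(list.files(root, recursive = TRUE))
  vapply(files, function(f) paste(readLines(file.path(root, f)), collapse = "\n"),
         character(1))
}
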