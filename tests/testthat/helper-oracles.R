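# Independent slow oracles used to cross-check fast implementations.

# Minimum number of monophyletic blocks covering `derived`: exhaustive
# search over set partitions (Bell number is small for <= 6 taxa), using
# ape::is.monophyletic as the independent clade test.
partition_clade_count <- function(tree, derived) {
  if (length(derived) == 1) return(1L)
  parts <- partitions_of(derived)
  sizes <- vapply(parts, length, integer(1))
  for (k in sort(unique(sizes))) {
    for (p in parts[sizes == k]) {
      ok <- all(vapply(p, function(block) {
        length(block) == 1 || ape::is.monophyletic(tree, block)
      }, logical(1)))
      if (ok) return(k)
    }
  }
  length(derived)
}

partitions_of <- function(x) {
  if (length(x) == 1) return(list(list(x)))
  rest <- partitions_of(x[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(x[1], q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(x[1]), p)
  }
  out
}

random_ultrametric <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rcoal(n)
  tr$tip.label <- paste0("s", seq_len(n))
  tr
}

# deterministic ultrametric tree with all edges >= 0.5, for exact-linear
# conversion fixtures whose subs/site lengths must stay positive
deep_ultrametric <- function() {
  ape::read.tree(text = paste0(
    "((A:1,(B:0.5,C:0.5):0.5):1.5,((D:0.8,E:0.8):0.9,F:1.7):0.8);"))
}
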