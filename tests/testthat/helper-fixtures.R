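# shared in-code fixtures

# small abundance table: 4 taxa x 3 samples, counts
toy_table <- function() {
  m <- matrix(c(1, 3, 0, 2,
                3, 1, 2, 0,
                2, 2, 1, 1), nrow = 4,
              dimnames = list(c("A", "B", "C", "D"), c("s1", "s2", "s3")))
  community_table(m)
}

# ((A:1,B:1):1,C:2); : d(A,B)=2, d(A,C)=d(B,C)=4
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# two tight star clades (within-clade tip distance `within`) separated by a
# long stem (between-clade distance `between + within`)
two_clade_tree <- function(within = 0.05, between = 0.5, n_each = 10) {
  nw_clade <- function(prefix) {
    tips <- paste0(prefix, seq_len(n_each), ":", within / 2)
    sprintf("(%s)", paste(tips, collapse = ","))
  }
  txt <- sprintf("(%s:%f,%s:%f);", nw_clade("a"), between / 2,
                 nw_clade("b"), between / 2)
  ape::read.tree(text = txt)
}

# random abundance table over a given tree's tips
random_table <- function(tree, n_samples = 4, seed = 1) {
  set.seed(seed)
  n <- length(tree$tip.label)
  m <- matrix(rpois(n * n_samples, 5) + 1, nrow = n,
              dimnames = list(tree$tip.label,
                              paste0("s", seq_len(n_samples))))
  community_table(m)
}

write_tsv_fixture <- function(df, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE)
  path
}
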