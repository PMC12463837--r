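kenya_fst_pairs.csv / kenya_ldn_pairs.csv
  Published pairwise population differentiation (F_ST) and lexical distance
  (LDN) values for four Kenyan populations (Luhya, Kikuyu, Maasai,
  Kalenjin), as printed in the literature, rounded to two decimals.  These
  are reference values for the matrix-comparison machinery, NOT
  recomputations from a wordlist.  Note only four of the six pairs over
  the four populations are published, so a full 4x4 matrix cannot be
  assembled; analyses use the complete Luhya/Kikuyu/Maasai triangle
  (read_matrix(..., keep = c("Luhya", "Kikuyu", "Maasai"))).

toy_wordlist.csv
  A small invented (synthetic) wordlist in the package's input format:
  header = glosses, column 1 = variety, column 2 = family, "" / NA / ? =
  missing form.  For examples and I/O tests only; not real lexical data.
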