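# Fixture tables

Nearest-neighbor contingency tables (NNCTs) and reduced Q-symmetry tables
for the black oak / maple / white oak subset (1097 trees) of the classic
Lansing Woods tree census (the `lansing` data set of the spatstat package;
924 ft x 924 ft plot, Clinton County, MI). The counts are transcribed from a
published symmetry analysis of this subset; raw coordinates are not shipped,
so these tables are used as-is for table-level tests.

Files:

- `lansing_nnct.csv` / `lansing_qsym.csv`: full 3-class NNCT and reduced
  (serving counts >= 2 pooled) Q-symmetry table.
- `lansing_nnct_pair_*.csv` / `lansing_qsym_pair_*.csv`: restricted pairwise
  tables, rebuilt from the two named species only.
- `lansing_nnct_ovr_*.csv` / `lansing_qsym_ovr_*.csv`: one-versus-rest
  tables (named species vs all others pooled).

Known defect: `lansing_qsym_ovr_maple_as_printed.csv` is internally
inconsistent as transcribed (its maple row sums to 519, not the 514 maples
in the data). `lansing_qsym_ovr_maple_corrected.csv` changes the single
entry 148 -> 143, the unique value restoring the row sum and the grand
total; the corrected table reproduces the published Pearson statistic
(16.125) exactly, supporting the correction.
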