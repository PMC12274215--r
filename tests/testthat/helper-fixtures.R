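# Tiny hand-built fixtures used across test files.

# two-node identity curve: ages 2 and 3, M 80 -> 86, S constant 0.04-style SD
tiny_height_curve <- function() {
  reference_curve("height", "male",
                  data.frame(age_years = c(2, 3), L = c(1, 1),
                             M = c(80, 86), S = c(3, 3)))
}

# two-node skewed curve with varying L, M, S
tiny_boxcox_curve <- function() {
  reference_curve("weight", "female",
                  data.frame(age_years = c(2, 3), L = c(-1.2, -1.0),
                             M = c(12.0, 13.0), S = c(0.10, 0.12)))
}

# minimal valid-looking bundle for I/O tests (domain rules intentionally
# not satisfied, so validated via structure-only paths)
write_tiny_csv <- function(path,
                           rows = data.frame(
                             parameter = "height", sex = "male",
                             age_years = c(0, 20), L = 1,
                             M = c(47, 131), S = c(2, 5))) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}
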