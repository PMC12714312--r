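# Small fixtures built in code.

# Constant-mortality life table: q at every age, terminal q = 1.
flat_life_table <- function(q, n_ages = 40, start_age = 67) {
  lt <- data.frame(age = seq(start_age, start_age + n_ages),
                   q = c(rep(q, n_ages), 1))
  structure(lt, class = c("life_table", "data.frame"))
}

zero_mortality_table <- function(n_ages = 40, start_age = 67) {
  flat_life_table(0, n_ages, start_age)
}

base_params <- function(...) model_parameters(...)
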