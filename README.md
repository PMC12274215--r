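# agrowth

Automated LMS-based growth assessment for children with achondroplasia.

Achondroplasia, the most common skeletal dysplasia, causes disproportionate
short stature: standard pediatric growth charts misclassify these children,
so clinical follow-up relies on disorder-specific reference charts. Reading
those charts by hand — looking up the age- and sex-specific coefficients,
interpolating between tabulated ages, applying the transformation and
converting to a percentile — is slow and error-prone, particularly when nine
anthropometric parameters are tracked per visit. `agrowth` automates the
whole calculation for pediatric endocrinologists, auxologists and clinical
researchers, and ships the synthetic machinery to verify it end to end.

## The model

Growth references are stored in Cole's LMS form: for each parameter and sex,
three curves over age — the Box-Cox power **L(t)** (normalising skewness),
the median **M(t)**, and the scale **S(t)**. For a measurement *X* at age
*t*, coefficients are obtained by piecewise-linear interpolation of L, M and
S between the two tabulated ages bracketing *t*, then:

- **Identity mode** (height, head circumference, sitting height, leg length,
  arm span, relative sitting height, foot length — charts tabulate L = 1,
  S as an absolute SD in measurement units):

      Z = (X − M) / S

- **Box-Cox mode** (weight, BMI — skewed distributions, S as a coefficient
  of variation):

      Z = ((X/M)^L − 1) / (L·S),    with   Z = ln(X/M)/S   as |L| → 0

The percentile is 100·Φ(Z) with Φ the standard normal CDF. The inverse
transform X(Z) = M·(1 + L·S·Z)^(1/L) (identity: M + Z·S) draws centile
curves and generates synthetic cohorts with known true z.

Supported parameters and age domains: height, weight, BMI and head
circumference from birth to 20 years; sitting height, leg length, arm span
and relative sitting height from 2 to 20 years; foot length from 3 to 20
years. BMI, leg length (height − sitting height) and relative sitting
height (100·sitting/height) are derived automatically when not measured
directly.

The coefficients of the published European achondroplasia charts are not
redistributable here; the package defines the bundle schema
(`parameter,sex,age_years,L,M,S` CSV, or nested JSON), a validator, and a
seeded synthetic generator that emulates their structure (18 curves,
6-month grid to age 4 then annual for the birth-to-20 parameters, annual
otherwise). Users load their own licensed coefficient bundle for clinical
use.

## Worked example

```r
library(agrowth)

ref <- load_reference(system.file("extdata", "synthetic_reference.csv",
                                  package = "agrowth"))

rec <- patient_record("ex01", "male", 6.25,
                      c(height = 95.0, weight = 27.3, sitting_height = 64.1,
                        head_circumference = 55.1))
assess_patient(rec, ref)
```

```
Assessment: patient ex01 (male, age 6.25 y)
               parameter    value     z percentile
                  height 95.00000 -0.91       18.1
                  weight 27.30000  0.65       74.2
                     bmi 30.24931  2.46       99.3
      head_circumference 55.10000  0.67       74.9
          sitting_height 64.10000  0.76       77.7
              leg_length 30.90000  1.57       94.2
 relative_sitting_height 67.47368 -0.51       30.6
                          flags
               interpolated_age
               interpolated_age
 interpolated_age;derived_input
               interpolated_age
               interpolated_age
 interpolated_age;derived_input
 interpolated_age;derived_input
```

Each row reports the measurement's z-score against the (synthetic)
reference and the percentile 100·Φ(z): this child's height sits at the 18th
percentile of the achondroplasia-specific reference while the BMI of 30.2
kg/m² (derived from weight and height, hence `derived_input`) lies at the
99th — the high-BMI pattern typical of the condition. Age 6.25 y falls
between the annual grid nodes, so every row carries `interpolated_age`;
`extreme_percentile` would flag |z| > 3. Foot length and arm span were not
measured and simply do not appear; parameters outside their age domain are
listed under `skipped` with a reason rather than aborting the record.

Batch files and chart tables use the same engine:

```r
batch_process("patients.csv", ref, "scored.csv")   # audited long-format output
centile_table(ref, "height", "male", percentiles = c(5, 50, 95))
```

A command-line front end is installed with the package (find it with
`system.file("exec", "agrowth", package = "agrowth")`): subcommands
`zscore`, `batch`, `curves`, `validate-ref`, `simulate` and `agreement`,
with exit codes 0 (success), 1 (validation failure), 2 (I/O or usage
error).

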