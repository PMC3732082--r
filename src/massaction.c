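/* Generic mass-action derivative evaluator for deSolve.
 *
 * The network is packed on the R side (pack_network) into a flat double
 * vector: [nreact | record * nreact], each record REC_W = 21 doubles:
 *   [0] law code (0 mass action, 1 hill inhibition, 2 time-gated, 3 constant,
 *       4 power law)
 *   [1] k   [2] p1   [3] p2
 *   [4] n rate species, [5..7] 1-based species indices
 *   [8] n changes, [9..20] (index, weight) pairs
 *
 * Parameters are fetched through deSolve's get_deSolve_gparms so the packed
 * vector can have arbitrary length.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <Rmath.h>

#define REC_W 21

static double *rc_p = NULL;

typedef SEXP (*gparms_fun)(void);
static gparms_fun rc_get_gparms = NULL;

void rc_initmod(void (*odeparms)(int *, double *))
{
    if (rc_get_gparms == NULL)
        rc_get_gparms = (gparms_fun) R_GetCCallable("deSolve", "get_deSolve_gparms");
    SEXP p = rc_get_gparms();
    if (TYPEOF(p) != REALSXP)
        error("rodcascade: packed network must be a double vector");
    rc_p = REAL(p);
}

void rc_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    int i, j;
    const double *p = rc_p;
    int nreact = (int) p[0];

    for (i = 0; i < *neq; i++) ydot[i] = 0.0;

    for (i = 0; i < nreact; i++) {
        const double *r = p + 1 + i * REC_W;
        int law = (int) r[0];
        double k = r[1], p1 = r[2], p2 = r[3];
        int nr = (int) r[4];
        double rate = 0.0;

        switch (law) {
        case 0: /* mass action */
            rate = k;
            for (j = 0; j < nr; j++)
                rate *= y[(int) r[5 + j] - 1];
            break;
        case 1: { /* hill inhibition: k / (1 + (x/K)^m) */
            double x = y[(int) r[5] - 1];
            if (x < 0.0) x = 0.0;
            rate = k / (1.0 + R_pow(x / p1, p2));
            break;
        }
        case 2: /* time-gated first order */
            rate = (*t >= p1 && *t < p2) ? k * y[(int) r[5] - 1] : 0.0;
            break;
        case 3: /* constant */
            rate = k;
            break;
        case 4: { /* power law: k * x^p1 */
            double x = y[(int) r[5] - 1];
            if (x < 0.0) x = 0.0;
            rate = k * R_pow(x, p1);
            break;
        }
        case 5: { /* mass action * exp(p1 * (x_last/p2 - 1)) */
            rate = k;
            for (j = 0; j < nr - 1; j++)
                rate *= y[(int) r[5 + j] - 1];
            rate *= exp(p1 * (y[(int) r[5 + nr - 1] - 1] / p2 - 1.0));
            break;
        }
        default:
            error("rodcascade: unknown rate law code %d", law);
        }

        {
            int ns = (int) r[8];
            for (j = 0; j < ns; j++) {
                int si = (int) r[9 + 2 * j] - 1;
                ydot[si] += r[10 + 2 * j] * rate;
            }
        }
    }
}
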