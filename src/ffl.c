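/* Compiled right-hand side of the two-equation FFL model for deSolve.
 *
 * Parameter vector (set via ffl_initmod, in this order):
 *  0 gamma_y  1 gamma_z  2 omega_yx  3 omega_zx  4 omega_zy  5 omega_zxy
 *  6 alpha_x  7 beta_x   8 beta_y    9 beta_xy  10 delta_y  11 delta_z
 * 12 n       13 m       14 x_active
 *
 * State: y[0] = Y, y[1] = Z. X is the constant active-input level.
 */
#include <R.h>
#include <math.h>

static double parms[15];

void ffl_initmod(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, parms);
}

void ffl_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double xn = pow(parms[14], parms[12]);
    double ym = pow(y[0] < 0 ? 0 : y[0], parms[13]);

    ydot[0] = parms[0] * (1 + parms[6] * parms[2] * xn) /
                  (1 + parms[2] * xn) -
              parms[10] * y[0];
    ydot[1] = parms[1] *
                  (1 + parms[7] * parms[3] * xn + parms[8] * parms[4] * ym +
                   parms[9] * parms[5] * xn * ym) /
                  (1 + parms[3] * xn + parms[4] * ym + parms[5] * xn * ym) -
              parms[11] * y[1];
}
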