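level1,code1,level2,code2,short_name,description
Meal,1,Staple,1-1,ST,Rice is the major component with some meat and eggs (rice soup; fried rice)
Meal,1,Noodles and dumplings,1-2,ND,Wheat and rice are the main components with some meat and vegetables
Meal,1,Set meal,1-3,SET,"Rice, meat or egg, and vegetables are the main components"
Meal,1,Seafood,1-4,SF,"Seafood, fish and other aquatic products with a small amount of vegetables and grains"
Meal,1,Pot,1-5,POT,"Vegetables, soy products, and aquatic products are the main ingredients (hotpot; dry pot)"
Meal,1,Fried and BBQ,1-6,F_BBQ,"Meat is the main food, cooked, fried, or smoked"
Meal,1,Western fast-food,1-7,WFF,Western fast-food (hamburger; pizza)
Meal,1,Healthy and light recipes,1-8,HLR,Average food from 80 percent of the food groups
Snacks and Beverage,2,Dessert,2-1,DT,Snacks and beverages sold separately (cakes; doughnut; ice cream)
Snacks and Beverage,2,Snacks,2-2,SK,"Non-ready-to-eat chicken wings, packed nuts, popcorn, grilled sausage"
Snacks and Beverage,2,Alcoholic beverage,2-3,AB,"Beer, wine, rice wine, sake and other drinks containing alcohol"
Snacks and Beverage,2,Synthetic beverage,2-4,SB,"Cola, Sprite and other carbonated drinks; fruit drinks; other synthetic drinks"
Snacks and Beverage,2,Stimulating drinks,2-5,SD,"Functional drinks, tea, coffee"
Other,3,Unknown,3-1,UN,Any food and food outlets outside of the above categories
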